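state,projected_population_2022,n_centres
Andaman & Nicobar Islands,402000,0
Andhra Pradesh,90879000,13
Arunachal Pradesh,1548000,1
Assam,35378000,12
Bihar,124919000,8
Chandigarh,1219000,5
Chhattisgarh,29836000,7
Dadra & Nagar Haveli and Daman & Diu,1170000,0
Delhi,20965000,15
Goa,1567000,15
Gujarat,70648000,14
Haryana,29846000,6
Himachal Pradesh,7431000,7
Jammu & Kashmir,13804000,6
Jharkhand,38969000,6
Karnataka,67268000,12
Kerala,35633000,234
Lakshadweep,68000,1
Madhya Pradesh,85548000,9
Maharashtra,125411000,22
Manipur,3194000,3
Meghalaya,3318000,1
Mizoram,1227000,7
Nagaland,2213000,3
Odisha,44162000,6
Puducherry,1608000,4
Punjab,30535000,8
Rajasthan,80153000,9
Sikkim,683000,2
Tamil Nadu,76631000,44
Telangana,37907000,18
Tripura,4109000,1
Uttar Pradesh,233297000,12
Uttarakhand,11518000,5
West Bengal,98604000,10
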