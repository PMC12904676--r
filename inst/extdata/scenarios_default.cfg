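# Standard service-delivery scenarios: tier unions evaluated in order.
I = PCC+TH+DH
II = PCC+TH+DH+CHC
III = PCC+TH+DH+CHC+PHC
IV = TH+DH+CHC+PHC
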