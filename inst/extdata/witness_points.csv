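"policy","delta","rho","gamma","r_l","r_min","expected_code"
"risky",0.05,0.2,0.9,0.5,0.3,"OS-"
"risky",0.05,0.2,0.9,0.5,0.6,"O--"
"risky",0.3,0.3,0.99,0.9,0.1,"-S-"
"risky",0.5,0.2,0.9,0.5,0.45,"---"
"cautious",0.5,0.2,0.9,0.5,0.3,"OSF"
"cautious",0.5,0.2,0.9,0.5,0.7,"O-F"
"cautious",0.05,0.2,0.9,0.5,0.3,"-SF"
"cautious",0.05,0.2,0.9,0.5,0.7,"--F"
"risky",0.05,0.45,1,0.5,0.3,"OS-"
"risky",0.2,0.4,1,0.5,0.7,"O--"
"risky",0.2,0.4,1,0.9,0.1,"-S-"
"risky",0.2,0.4,1,0.9,0.8,"---"
"cautious",0.5,0.2,1,0.5,0.3,"OSF"
"cautious",0.5,0.2,1,0.5,0.7,"O-F"
"cautious",0.05,0.45,1,0.5,0.3,"-SF"
"cautious",0.05,0.45,1,0.5,0.7,"--F"
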