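scorer,net,net,net,net,net,net,net,net,net,net,net,net,net,net,net,net,net,net,net,net,net
bodyparts,ear_left,ear_left,ear_left,ear_right,ear_right,ear_right,eyelid_upper_left,eyelid_upper_left,eyelid_upper_left,eyelid_lower_left,eyelid_lower_left,eyelid_lower_left,eyelid_upper_right,eyelid_upper_right,eyelid_upper_right,eyelid_lower_right,eyelid_lower_right,eyelid_lower_right,nose,nose,nose
coords,x,y,likelihood,x,y,likelihood,x,y,likelihood,x,y,likelihood,x,y,likelihood,x,y,likelihood,x,y,likelihood
0,100.5,40.25,0.99,300,41,0.98,140,100,1,140,124,0.97,260,101,0.96,260,125,0.95,200.75,250.5,0.94
1,101.5,41.25,0.89,301,42,0.88,141,101,0.9,141,125,0.87,261,102,0.86,261,126,0.85,201.75,251.5,0.84
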