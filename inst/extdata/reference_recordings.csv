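recording,bpm,b_bar,s_bar,sigma_b,sigma_s,r,delta_r,rho_b_to_s,rho_s_to_b
Alfie's Theme,135,1,634,16.94,18.3,1.99,0.39,0.22,0.51
Blue Monk,140,0,627,18.85,17.5,1.93,0.39,0.43,0.57
Don't Get Around Much Anymore,140,24,644,20.44,19.18,2.11,0.51,0.48,0.51
Doxy,130,1,624,15.31,17.85,1.89,0.33,0.21,0.59
Four,170,3,602,17.7,17.01,1.73,0.38,0.67,0.75
In a Mellow Tone,160,-7,623,20.1,21.79,1.94,0.58,0.72,0.69
Jordu,150,-1,603,19.11,17.31,1.73,0.33,0.39,0.66
Now's The Time,190,-20,582,15.55,21.01,1.62,0.45,0.53,0.73
Paper Moon,135,-2,635,18.73,17.34,2.0,0.41,0.41,0.46
Serenade to a Cuckoo,140,22,634,21.6,20.15,2.0,0.42,0.1,0.59
So What,160,4,582,18.48,15.59,1.57,0.32,0.67,0.8
Yardbird Suite,180,7,596,21.12,20.38,1.71,0.51,0.59,0.53
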