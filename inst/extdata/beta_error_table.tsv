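nsnps	cov	error
10	20	0.176025209228464
25	20	0.139475178191334
50	20	0.119114589091793
100	20	0.0924541728205075
200	20	0.0791711779787423
10	50	0.11314568762415
25	50	0.089866000115863
50	50	0.0748481679032718
100	50	0.0623385738457088
200	50	0.050848940267118
10	100	0.0800003925821504
25	100	0.0610881280410514
50	100	0.0526945168890103
100	100	0.0435684556864864
200	100	0.0355276246179487
10	200	0.0575998916246329
25	200	0.0446463421956873
50	200	0.0354539036155081
100	200	0.0307495431808851
200	200	0.0253562419004901
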