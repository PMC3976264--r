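mir,mean_low,mean_high,ddct,fold_change,p_value,q_value
miR222,22.6284,25.6460,3.017597,8.098176,0.013078,0.057554
miR16,22.7880,25.8020,3.014036,8.078210,0.024273,0.057554
miR205,25.8730,28.5610,2.687978,6.444098,0.038138,0.057554
miR20a,25.2013,27.8736,2.672283,6.374369,0.042064,0.057554
miR331,26.5414,29.1520,2.610608,6.107610,0.037799,0.057554
miR21,25.6082,28.0528,2.444620,5.443823,0.039690,0.057554
miR375,25.4324,27.8130,2.380519,5.207240,0.029020,0.057554
miR34a,27.6115,29.8324,2.220869,4.661743,0.025066,0.057554
miR106b,28.2883,30.1729,1.884607,3.692524,0.045221,0.057554
miR221,28.4153,30.0484,1.633065,3.101714,0.060869,0.070955
miR182,29.2585,30.6111,1.352615,2.553746,0.028318,0.057554
miR145,29.3191,30.4363,1.117213,2.169275,0.065887,0.070955
miR218,26.1297,25.6887,-0.441010,0.736619,0.612671,0.612671
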