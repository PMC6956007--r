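Nit,a,b,c,d,F
25,255.7506,23.1953,344.3629,0.0000,185.6737
50,209.6757,21.3999,288.8835,0.0814,157.9571
100,233.4375,21.2668,266.9164,0.0492,154.7241
200,238.6861,21.1010,242.4651,0.0571,150.1093
300,244.5549,20.8891,239.7912,0.0777,145.6895
400,238.0263,20.1484,227.6343,0.1002,145.9515
500,220.6098,19.5167,212.1591,0.1091,142.7544
600,209.2398,18.9435,203.5418,0.1155,140.1229
700,208.3796,18.6725,200.2183,0.1180,138.9247
800,205.1722,18.6186,196.1978,0.1294,138.2120
900,206.8349,18.7251,195.6544,0.1247,137.1808
1000,204.2514,18.5038,192.3779,0.1250,135.9998
1100,201.7751,18.6313,191.4930,0.1164,136.7989
1200,199.1862,18.7457,190.4784,0.1237,136.2337
1300,196.8611,18.6375,190.3953,0.1201,135.1311
1400,198.3144,18.5702,190.7353,0.1230,135.3718
1500,196.1595,18.3109,189.0624,0.1306,134.3871
1600,192.2135,17.9623,185.5415,0.1447,133.7077
1700,190.5854,17.8516,183.7031,0.1508,133.3508
1800,190.7481,17.8419,184.6075,0.1495,133.5511
1900,192.3369,17.8900,185.2415,0.1473,133.6132
2000,194.9553,18.0284,185.7370,0.1495,133.5813
2100,198.5889,18.1381,187.4582,0.1452,134.3980
2200,200.3984,18.1539,188.0695,0.1366,134.8025
2300,201.9018,18.2673,188.5241,0.1356,134.8863
2400,201.6645,18.2587,187.8792,0.1357,135.2327
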