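T_K,P_bar,y,rho_gL,S_gL
303.15,90,2.18e-05,681.6,0.09674
303.15,115,2.92e-05,758.1,0.1441
303.15,130,3.58e-05,789,0.1839
303.15,140,4.12e-05,806.5,0.2162
303.15,155,5.29e-05,829.3,0.2855
303.15,175,6.01e-05,855.3,0.3345
303.15,185,6.25e-05,866.9,0.3527
303.15,195,7.21e-05,877.7,0.4118
303.15,220,7.96e-05,901.9,0.4672
303.15,230,8.19e-05,910.7,0.4854
303.15,245,8.32e-05,923,0.4998
313.15,100,1.68e-05,561.3,0.06136
313.15,120,3.62e-05,664.1,0.1565
313.15,130,5.41e-05,696.5,0.2453
313.15,140,5.25e-05,723.2,0.2471
313.15,155,6.63e-05,756.3,0.3263
313.15,170,8.13e-05,783.8,0.4148
313.15,200,1.255e-04,828.3,0.6766
313.15,235,1.38e-04,869.1,0.7808
313.15,245,1.492e-04,879.2,0.854
323.15,110,2.68e-05,462.2,0.08062
323.15,135,5.24e-05,603,0.2056
323.15,165,1.014e-04,693,0.4575
323.15,180,1.402e-04,725.3,0.6619
323.15,195,1.482e-04,752.6,0.726
323.15,205,1.6e-04,768.9,0.8008
323.15,235,1.964e-04,810.5,1.036
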