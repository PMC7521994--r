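LM3=12
0.262550 0.331620 0.254403
0.318996 0.366836 0.129812
0.666685 0.156462 0.168655
0.596846 0.188727 0.071157
0.489379 0.163633 -0.001356
0.233064 0.262390 0.336235
0.203903 0.135890 0.392177
0.591566 -0.005834 0.357468
0.477134 -0.057182 0.362097
0.367889 -0.089920 0.292064
0.632044 0.061511 0.253156
0.141122 0.212483 0.177593
ID=S0001
LM3=12
-0.342024 -0.617792 -0.505292
-0.304621 -0.752549 -0.559328
0.026471 -0.823276 -0.317274
-0.047880 -0.905664 -0.380731
-0.180529 -0.977142 -0.404245
-0.370960 -0.566229 -0.440523
-0.409391 -0.562683 -0.295697
-0.057343 -0.675451 -0.113731
-0.179003 -0.674895 -0.068562
-0.320641 -0.733263 -0.069845
-0.005775 -0.797026 -0.177212
-0.470880 -0.723719 -0.423740
ID=S0002
LM3=12
1.804433 -0.137679 0.059956
1.831250 -0.215203 0.181211
1.455400 -0.401152 0.291905
1.568447 -0.421736 0.333185
1.699942 -0.493719 0.277960
1.769409 -0.136215 -0.040187
1.717326 -0.220599 -0.159645
1.353648 -0.400699 -0.008778
1.415510 -0.416656 -0.108628
1.548156 -0.492294 -0.148912
1.395762 -0.464610 0.146075
1.887974 -0.291301 -0.028427
ID=S0003
LM3=12
0.072081 -0.411193 0.757365
0.244711 -0.362464 0.698876
0.069272 -0.075933 0.275834
0.194898 -0.071666 0.366296
0.243287 -0.015505 0.511324
-0.076957 -0.400397 0.800161
-0.243878 -0.308496 0.838572
-0.265899 -0.041469 0.362052
-0.322600 -0.019912 0.510407
-0.281877 0.039814 0.664405
-0.096778 0.005139 0.303637
0.049414 -0.249664 0.911819
ID=S0004
LM3=12
-0.465238 -0.458246 0.422577
-0.585550 -0.558014 0.372356
-0.853981 -0.279441 0.031832
-0.835029 -0.454086 0.059778
-0.715966 -0.565341 0.024070
-0.344494 -0.345250 0.389111
-0.255562 -0.263682 0.287639
-0.606092 -0.056790 -0.040233
-0.435437 -0.094139 -0.048938
-0.347436 -0.234991 -0.081129
-0.733223 -0.178380 -0.032625
-0.318220 -0.538458 0.296528
ID=S0005
LM3=12
0.922266 -0.406343 -0.188480
0.989690 -0.293228 -0.114224
0.876533 -0.314146 0.405181
1.005425 -0.238367 0.323623
1.175388 -0.251446 0.267020
0.898190 -0.555661 -0.197009
0.905433 -0.697197 -0.121460
0.815388 -0.661469 0.390264
0.899780 -0.776058 0.311151
1.069874 -0.823436 0.250325
0.842870 -0.487990 0.441654
1.097565 -0.519202 -0.172282
ID=S0006
LM3=12
0.167529 0.206534 0.511061
0.194852 0.111900 0.453479
-0.110538 0.044551 0.254706
-0.003018 0.034423 0.214498
0.100731 0.068772 0.184263
0.125921 0.306802 0.526142
0.067207 0.405400 0.492643
-0.208703 0.271261 0.286911
-0.147413 0.369509 0.261566
-0.057630 0.423746 0.233259
-0.164616 0.160957 0.246200
0.233276 0.314053 0.409224
ID=S0007
LM3=12
0.401980 0.210825 -0.014294
0.332540 0.336786 -0.063542
-0.122857 0.159526 -0.188149
-0.097695 0.306828 -0.161150
-0.042110 0.416742 -0.050092
0.410478 0.091739 0.101634
0.346795 0.020646 0.216876
-0.118089 -0.103434 0.055976
-0.075073 -0.092686 0.196918
-0.022688 0.007590 0.314485
-0.172151 0.027265 -0.064217
0.356383 0.281412 0.186084
ID=S0008
LM3=12
0.450071 -0.531572 0.189526
0.565796 -0.665890 0.199349
0.421816 -0.973871 -0.163480
0.532587 -0.964854 -0.067041
0.665245 -0.857526 -0.046528
0.392175 -0.426048 0.096853
0.399576 -0.348412 -0.054407
0.298635 -0.730472 -0.368928
0.345739 -0.591110 -0.381126
0.486446 -0.502399 -0.329648
0.374518 -0.860760 -0.283212
0.609125 -0.440289 0.077284
ID=S0009
LM3=12
-0.265267 0.755179 0.071948
-0.265098 0.805949 -0.083456
-0.123530 0.352471 -0.336166
-0.217933 0.485609 -0.422046
-0.377762 0.582975 -0.417619
-0.318154 0.627716 0.204741
-0.415135 0.498747 0.258691
-0.225947 0.128176 -0.097684
-0.390160 0.112368 -0.009290
-0.556843 0.203607 0.012182
-0.249244 0.205907 -0.270644
-0.523543 0.732948 0.081242
ID=S0010
LM3=12
0.027781 0.476716 -0.768894
0.109228 0.330590 -0.785952
0.387071 0.251207 -0.401219
0.343822 0.164128 -0.496761
0.199939 0.094403 -0.548778
-0.049548 0.571488 -0.673143
-0.120306 0.591651 -0.528491
0.207070 0.469192 -0.182840
0.066658 0.488503 -0.183214
-0.073417 0.410927 -0.232591
0.290949 0.327717 -0.259246
-0.134461 0.393246 -0.696310
ID=S0011
LM3=12
-1.397933 0.191356 -0.000974
-1.336072 0.138183 0.084716
-1.098313 0.419021 0.150090
-1.124836 0.357430 0.208206
-1.223522 0.295281 0.285944
-1.456210 0.266839 -0.046342
-1.519965 0.366890 -0.045082
-1.249230 0.598797 0.044957
-1.340066 0.611512 0.059528
-1.451698 0.577448 0.122596
-1.165341 0.531739 0.118413
-1.526645 0.223604 0.112260
ID=S0012
LM3=12
0.124095 -0.076436 0.729405
0.048079 0.026922 0.866600
-0.157191 0.459856 0.699021
-0.184843 0.394470 0.834254
-0.245000 0.237585 0.920791
0.081560 -0.135812 0.572941
-0.052871 -0.132105 0.452645
-0.240337 0.334228 0.365886
-0.311366 0.201046 0.334908
-0.382225 0.036033 0.405028
-0.281784 0.434617 0.542186
-0.098362 -0.213235 0.743193
ID=S0013
LM3=12
0.667176 -0.018215 -0.489672
0.612289 0.133282 -0.448005
0.688324 0.274994 0.044623
0.658464 0.379645 -0.060707
0.742440 0.417095 -0.242718
0.825973 -0.139081 -0.462149
0.972975 -0.134243 -0.404544
1.015641 0.034064 0.084053
1.141883 0.029829 -0.001023
1.166623 0.094748 -0.186938
0.869626 0.187426 0.106231
0.862241 0.060870 -0.582846
ID=S0014
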