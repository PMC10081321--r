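cell_type	dataset	score
Neural_Progenitor	synthetic_1	0.883517
Dividing_Progenitor	synthetic_1	0.808493
Intermediate_Progenitor	synthetic_1	0.708713
Glutamatergic	synthetic_1	0.804624
GABAergic	synthetic_1	0.957723
Non_neuronal	synthetic_1	0.935294
Neural_Progenitor	synthetic_2	0.925385
Dividing_Progenitor	synthetic_2	0.90129
Intermediate_Progenitor	synthetic_2	0.972381
Glutamatergic	synthetic_2	0.937559
GABAergic	synthetic_2	0.99956
Non_neuronal	synthetic_2	0.957754
Neural_Progenitor	synthetic_3	0.98575
Dividing_Progenitor	synthetic_3	0.982101
Intermediate_Progenitor	synthetic_3	0.953979
Glutamatergic	synthetic_3	0.994841
GABAergic	synthetic_3	0.980182
Non_neuronal	synthetic_3	0.949953
Neural_Progenitor	synthetic_4	0.981975
Dividing_Progenitor	synthetic_4	0.996099
Intermediate_Progenitor	synthetic_4	0.894338
Glutamatergic	synthetic_4	0.999025
GABAergic	synthetic_4	0.934854
Non_neuronal	synthetic_4	0.991601
Neural_Progenitor	synthetic_5	0.765304
Dividing_Progenitor	synthetic_5	0.69157
Intermediate_Progenitor	synthetic_5	0.770148
Glutamatergic	synthetic_5	0.847594
GABAergic	synthetic_5	0.905033
Non_neuronal	synthetic_5	0.642969
Neural_Progenitor	synthetic_6	0.691916
Dividing_Progenitor	synthetic_6	0.72894
Intermediate_Progenitor	synthetic_6	0.879648
Glutamatergic	synthetic_6	0.929726
GABAergic	synthetic_6	0.726769
Non_neuronal	synthetic_6	0.914879
Neural_Progenitor	synthetic_7	0.897295
Dividing_Progenitor	synthetic_7	0.837213
Intermediate_Progenitor	synthetic_7	0.732211
Glutamatergic	synthetic_7	0.766436
GABAergic	synthetic_7	0.813086
Non_neuronal	synthetic_7	0.827053
Neural_Progenitor	synthetic_8	0.813998
Dividing_Progenitor	synthetic_8	0.854923
Intermediate_Progenitor	synthetic_8	0.642969
Glutamatergic	synthetic_8	0.791853
GABAergic	synthetic_8	0.574048
Non_neuronal	synthetic_8	0.826707
Neural_Progenitor	synthetic_9	0.939069
Dividing_Progenitor	synthetic_9	0.973671
Intermediate_Progenitor	synthetic_9	0.943316
Glutamatergic	synthetic_9	0.909059
GABAergic	synthetic_9	0.9933
Non_neuronal	synthetic_9	0.962693
Neural_Progenitor	synthetic_10	0.780025
Dividing_Progenitor	synthetic_10	0.928405
Intermediate_Progenitor	synthetic_10	0.743819
Glutamatergic	synthetic_10	0.940642
GABAergic	synthetic_10	0.760711
Non_neuronal	synthetic_10	0.860805
Neural_Progenitor	synthetic_11	0.814155
Dividing_Progenitor	synthetic_11	0.803303
Intermediate_Progenitor	synthetic_11	0.887103
Glutamatergic	synthetic_11	0.967411
GABAergic	synthetic_11	0.802517
Non_neuronal	synthetic_11	0.849324
Neural_Progenitor	synthetic_12	0.85464
Dividing_Progenitor	synthetic_12	0.899874
Intermediate_Progenitor	synthetic_12	0.825511
Glutamatergic	synthetic_12	0.741774
GABAergic	synthetic_12	0.867065
Non_neuronal	synthetic_12	0.823404
Neural_Progenitor	synthetic_13	0.926486
Dividing_Progenitor	synthetic_13	0.799528
Intermediate_Progenitor	synthetic_13	0.901919
Glutamatergic	synthetic_13	0.68921
GABAergic	synthetic_13	0.749607
Non_neuronal	synthetic_13	0.683894
Neural_Progenitor	synthetic_14	0.998081
Dividing_Progenitor	synthetic_14	0.997483
Intermediate_Progenitor	synthetic_14	0.999811
Glutamatergic	synthetic_14	0.980528
GABAergic	synthetic_14	0.979679
Non_neuronal	synthetic_14	0.999654
Neural_Progenitor	synthetic_15	0.858037
Dividing_Progenitor	synthetic_15	0.93866
Intermediate_Progenitor	synthetic_15	0.875716
Glutamatergic	synthetic_15	0.956936
GABAergic	synthetic_15	0.881409
Non_neuronal	synthetic_15	0.759925
Neural_Progenitor	synthetic_16	0.965555
Dividing_Progenitor	synthetic_16	0.926455
Intermediate_Progenitor	synthetic_16	0.970242
Glutamatergic	synthetic_16	0.850676
GABAergic	synthetic_16	0.940673
Non_neuronal	synthetic_16	0.997892
Neural_Progenitor	synthetic_17	0.999811
Dividing_Progenitor	synthetic_17	0.999025
Intermediate_Progenitor	synthetic_17	0.999748
Glutamatergic	synthetic_17	0.999937
GABAergic	synthetic_17	1
Non_neuronal	synthetic_17	0.999025
Neural_Progenitor	synthetic_18	0.812425
Dividing_Progenitor	synthetic_18	0.747436
Intermediate_Progenitor	synthetic_18	0.720981
Glutamatergic	synthetic_18	0.91123
GABAergic	synthetic_18	0.704939
Non_neuronal	synthetic_18	0.721831
Neural_Progenitor	synthetic_19	0.930387
Dividing_Progenitor	synthetic_19	0.993457
Intermediate_Progenitor	synthetic_19	0.967443
Glutamatergic	synthetic_19	0.883234
GABAergic	synthetic_19	0.943347
Non_neuronal	synthetic_19	0.945203
Neural_Progenitor	synthetic_20	0.971375
Dividing_Progenitor	synthetic_20	0.84039
Intermediate_Progenitor	synthetic_20	0.96263
Glutamatergic	synthetic_20	0.968512
GABAergic	synthetic_20	0.997012
Non_neuronal	synthetic_20	0.997987
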