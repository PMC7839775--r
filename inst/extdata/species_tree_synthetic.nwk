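(((((Species_14:0.03333333333,Species_02:0.03333333333):0.03333333333,Species_16:0.06666666667):0.06666666667,(Species_24:0.03333333333,Species_15:0.03333333333):0.1):0.4666666667,((Species_05:0.06666666667,(Species_23:0.03333333333,Species_11:0.03333333333):0.03333333333):0.3666666667,((((Species_07:0.1,(Species_19:0.06666666667,(Species_25:0.03333333333,Species_30:0.03333333333):0.03333333333):0.03333333333):0.1,((Species_31:0.03333333333,Species_22:0.03333333333):0.03333333333,Species_12:0.06666666667):0.1333333333):0.06666666667,(Species_08:0.03333333333,Species_06:0.03333333333):0.2333333333):0.06666666667,(Species_18:0.03333333333,Species_09:0.03333333333):0.3):0.1):0.1666666667):0.4,((((Species_03:0.03333333333,Species_17:0.03333333333):0.06666666667,(Species_20:0.03333333333,Species_04:0.03333333333):0.06666666667):0.03333333333,Species_28:0.1333333333):0.2333333333,((Species_21:0.03333333333,Species_27:0.03333333333):0.1666666667,(Species_01:0.1333333333,((Species_13:0.03333333333,Species_10:0.03333333333):0.06666666667,(Species_29:0.03333333333,Species_26:0.03333333333):0.06666666667):0.03333333333):0.06666666667):0.1666666667):0.6333333333);
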