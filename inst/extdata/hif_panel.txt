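# supervised feature panel: sparse HIF-1/HIF-2 target genes
HIF1T_01
HIF1T_02
HIF1T_03
HIF1T_04
HIF1T_05
HIF1T_06
HIF1T_07
HIF1T_08
HIF1T_09
HIF1T_10
HIF1T_11
HIF1T_12
HIF1T_13
HIF1T_14
HIF1T_15
HIF1T_16
HIF1T_17
HIF1T_18
HIF1T_19
HIF1T_20
HIF1T_21
HIF1T_22
HIF1T_23
HIF1T_24
HIF1T_25
HIF1T_26
HIF1T_27
HIF1T_28
HIF1T_29
HIF1T_30
HIF1T_31
HIF1T_32
HIF1T_33
HIF1T_34
HIF1T_35
HIF2T_01
HIF2T_02
HIF2T_03
HIF2T_04
HIF2T_05
HIF2T_06
HIF2T_07
HIF2T_08
HIF2T_09
HIF2T_10
HIF2T_11
HIF2T_12
HIF2T_13
HIF2T_14
HIF2T_15
HIF2T_16
HIF2T_17
HIF2T_18
HIF2T_19
HIF2T_20
HIF2T_21
HIF2T_22
HIF2T_23
HIF2T_24
HIF2T_25
HIF2T_26
HIF2T_27
HIF2T_28
HIF2T_29
HIF2T_30
HIF2T_31
HIF2T_32
HIF2T_33
HIF2T_34
HIF2T_35
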