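sample_id	condition	mutation
case_01	case	JAK2V617F
case_02	case	MPLW515
case_03	case	JAK2V617F
case_04	case	CALR
case_05	case	JAK2V617F
case_06	case	JAK2V617F
case_07	case	JAK2V617F
case_08	case	JAK2V617F
ctrlA_01	ctrlA	none
ctrlA_02	ctrlA	none
ctrlA_03	ctrlA	none
ctrlA_04	ctrlA	none
ctrlA_05	ctrlA	none
ctrlA_06	ctrlA	none
ctrlA_07	ctrlA	none
ctrlA_08	ctrlA	none
ctrlB_01	ctrlB	none
ctrlB_02	ctrlB	none
ctrlB_03	ctrlB	none
ctrlB_04	ctrlB	none
ctrlB_05	ctrlB	none
ctrlB_06	ctrlB	none
ctrlB_07	ctrlB	none
ctrlB_08	ctrlB	none
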