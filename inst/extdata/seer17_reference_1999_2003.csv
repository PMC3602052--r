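group,period,object_id,stage,n_stage,n_total,rel_surv
SEER17,1999-2003,1,0,167,191771,93.6
SEER17,1999-2003,1,1,83081,191771,100.00
SEER17,1999-2003,1,2,72195,191771,90.2
SEER17,1999-2003,1,3,12617,191771,61.3
SEER17,1999-2003,1,4,8449,191771,22.5
SEER17,1999-2003,1,5,15262,191771,77.3
SEER17,1999-2003,1,6,191771,191771,89.1
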