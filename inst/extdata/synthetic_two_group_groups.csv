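cell_id,group
cell001,C10like
cell002,C10like
cell003,C10like
cell004,C10like
cell005,C10like
cell006,C10like
cell007,C10like
cell008,C10like
cell009,C10like
cell010,C10like
cell011,C10like
cell012,C10like
cell013,SVEClike
cell014,SVEClike
cell015,SVEClike
cell016,SVEClike
cell017,SVEClike
cell018,SVEClike
cell019,SVEClike
cell020,SVEClike
cell021,SVEClike
cell022,SVEClike
cell023,SVEClike
cell024,SVEClike
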