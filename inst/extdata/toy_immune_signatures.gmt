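ACT_CD8_T	toy synthetic signature: ACT_CD8_T	IMM_CD8_01	IMM_CD8_02	IMM_CD8_03	IMM_CD8_04	IMM_CD8_05	IMM_CD8_06	IMM_CD8_07	IMM_CD8_08	IMM_CD8_09	IMM_CD8_10
ACT_B_CELL	toy synthetic signature: ACT_B_CELL	IMM_B_01	IMM_B_02	IMM_B_03	IMM_B_04	IMM_B_05	IMM_B_06	IMM_B_07	IMM_B_08	IMM_B_09	IMM_B_10
NK_CELL	toy synthetic signature: NK_CELL	IMM_NK_01	IMM_NK_02	IMM_NK_03	IMM_NK_04	IMM_NK_05	IMM_NK_06	IMM_NK_07	IMM_NK_08	IMM_NK_09	IMM_NK_10
MACROPHAGE	toy synthetic signature: MACROPHAGE	IMM_MAC_01	IMM_MAC_02	IMM_MAC_03	IMM_MAC_04	IMM_MAC_05	IMM_MAC_06	IMM_MAC_07	IMM_MAC_08	IMM_MAC_09	IMM_MAC_10
ACT_DC	toy synthetic signature: ACT_DC	IMM_DC_01	IMM_DC_02	IMM_DC_03	IMM_DC_04	IMM_DC_05	IMM_DC_06	IMM_DC_07	IMM_DC_08	IMM_DC_09	IMM_DC_10
TFH_CELL	toy synthetic signature: TFH_CELL	IMM_TFH_01	IMM_TFH_02	IMM_TFH_03	IMM_TFH_04	IMM_TFH_05	IMM_TFH_06	IMM_TFH_07	IMM_TFH_08	IMM_TFH_09	IMM_TFH_10
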