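individual_id,population_id,initial_stage,final_stage,recruits
meadow_1,meadow,juv,sub,
meadow_2,meadow,juv,DEAD,
meadow_3,meadow,juv,DEAD,
meadow_4,meadow,juv,juv,
meadow_5,meadow,juv,DEAD,
meadow_6,meadow,juv,DEAD,
meadow_7,meadow,juv,juv,
meadow_8,meadow,juv,DEAD,
meadow_9,meadow,juv,DEAD,
meadow_10,meadow,juv,DEAD,
meadow_11,meadow,juv,juv,
meadow_12,meadow,juv,juv,
meadow_13,meadow,juv,sub,
meadow_14,meadow,juv,sub,
meadow_15,meadow,juv,DEAD,
meadow_16,meadow,juv,DEAD,
meadow_17,meadow,juv,DEAD,
meadow_18,meadow,juv,DEAD,
meadow_19,meadow,juv,DEAD,
meadow_20,meadow,juv,sub,
meadow_21,meadow,juv,DEAD,
meadow_22,meadow,juv,DEAD,
meadow_23,meadow,sub,sub,
meadow_24,meadow,sub,adult,
meadow_25,meadow,sub,sub,
meadow_26,meadow,sub,sub,
meadow_27,meadow,sub,sub,
meadow_28,meadow,sub,sub,
meadow_29,meadow,sub,adult,
meadow_30,meadow,sub,sub,
meadow_31,meadow,sub,adult,
meadow_32,meadow,sub,sub,
meadow_33,meadow,sub,DEAD,
meadow_34,meadow,sub,adult,
meadow_35,meadow,sub,sub,
meadow_36,meadow,sub,sub,
meadow_37,meadow,sub,sub,
meadow_38,meadow,sub,sub,
meadow_39,meadow,sub,sub,
meadow_40,meadow,sub,sub,
meadow_41,meadow,sub,adult,
meadow_42,meadow,sub,adult,
meadow_43,meadow,sub,sub,
meadow_44,meadow,sub,DEAD,
meadow_45,meadow,sub,adult,
meadow_46,meadow,adult,adult,juv:2
meadow_47,meadow,adult,adult,juv:1
meadow_48,meadow,adult,DEAD,juv:1
meadow_49,meadow,adult,adult,juv:2
meadow_50,meadow,adult,adult,juv:2
forest_1,forest,juv,juv,
forest_2,forest,juv,DEAD,
forest_3,forest,juv,DEAD,
forest_4,forest,juv,DEAD,
forest_5,forest,juv,DEAD,
forest_6,forest,juv,sub,
forest_7,forest,juv,DEAD,
forest_8,forest,juv,DEAD,
forest_9,forest,juv,DEAD,
forest_10,forest,juv,juv,
forest_11,forest,juv,DEAD,
forest_12,forest,juv,DEAD,
forest_13,forest,juv,DEAD,
forest_14,forest,juv,DEAD,
forest_15,forest,juv,DEAD,
forest_16,forest,juv,sub,
forest_17,forest,juv,sub,
forest_18,forest,juv,DEAD,
forest_19,forest,juv,DEAD,
forest_20,forest,sub,sub,
forest_21,forest,sub,adult,
forest_22,forest,sub,sub,
forest_23,forest,sub,adult,
forest_24,forest,sub,adult,
forest_25,forest,sub,adult,
forest_26,forest,sub,adult,
forest_27,forest,sub,adult,
forest_28,forest,sub,sub,
forest_29,forest,sub,adult,
forest_30,forest,sub,sub,
forest_31,forest,sub,sub,
forest_32,forest,sub,sub,
forest_33,forest,sub,sub,
forest_34,forest,adult,DEAD,juv:2
forest_35,forest,adult,DEAD,juv:1
forest_36,forest,adult,DEAD,juv:2
forest_37,forest,adult,adult,juv:5
forest_38,forest,adult,adult,juv:2
forest_39,forest,adult,adult,juv:2
forest_40,forest,adult,adult,juv:2
forest_41,forest,adult,DEAD,juv:3
forest_42,forest,adult,adult,juv:3
forest_43,forest,adult,DEAD,juv:2
forest_44,forest,adult,adult,juv:5
forest_45,forest,adult,adult,juv:2
forest_46,forest,adult,adult,juv:1
forest_47,forest,adult,adult,juv:1
forest_48,forest,adult,DEAD,juv:1
forest_49,forest,adult,adult,juv:3
forest_50,forest,adult,adult,juv:1
coast_1,coast,juv,DEAD,
coast_2,coast,juv,DEAD,
coast_3,coast,juv,juv,
coast_4,coast,juv,DEAD,
coast_5,coast,juv,sub,
coast_6,coast,juv,sub,
coast_7,coast,juv,juv,
coast_8,coast,juv,DEAD,
coast_9,coast,juv,sub,
coast_10,coast,juv,juv,
coast_11,coast,juv,juv,
coast_12,coast,juv,sub,
coast_13,coast,juv,sub,
coast_14,coast,juv,DEAD,
coast_15,coast,juv,DEAD,
coast_16,coast,juv,sub,
coast_17,coast,juv,juv,
coast_18,coast,juv,sub,
coast_19,coast,juv,DEAD,
coast_20,coast,juv,sub,
coast_21,coast,juv,sub,
coast_22,coast,juv,sub,
coast_23,coast,juv,DEAD,
coast_24,coast,juv,sub,
coast_25,coast,juv,DEAD,
coast_26,coast,juv,DEAD,
coast_27,coast,sub,sub,
coast_28,coast,sub,adult,
coast_29,coast,sub,adult,
coast_30,coast,sub,adult,
coast_31,coast,sub,DEAD,
coast_32,coast,sub,DEAD,
coast_33,coast,sub,adult,
coast_34,coast,sub,sub,
coast_35,coast,sub,adult,
coast_36,coast,sub,sub,
coast_37,coast,sub,DEAD,
coast_38,coast,sub,sub,
coast_39,coast,sub,adult,
coast_40,coast,sub,sub,
coast_41,coast,sub,DEAD,
coast_42,coast,adult,adult,juv:1
coast_43,coast,adult,adult,juv:9
coast_44,coast,adult,DEAD,
coast_45,coast,adult,adult,juv:2
coast_46,coast,adult,adult,juv:1
coast_47,coast,adult,DEAD,juv:2
coast_48,coast,adult,DEAD,juv:2
coast_49,coast,adult,adult,juv:1
coast_50,coast,adult,adult,juv:3
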