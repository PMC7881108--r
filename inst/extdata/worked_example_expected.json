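{
  "visits": [1, 4, 1, 2, 1, 2, 6, 2, 0, 1, 3, 1, 3],
  "quad_windows": ["1412", "4121", "1212", "2126", "1262", "2620", "6201", "2013", "0131", "1313"],
  "quad_classes": ["forward_polling", "backwards_polling", "backwards_polling", "backwards_polling", "right_scenery", "right_scenery", "speed_monitoring", "speed_monitoring", "guidance", "guidance"],
  "triplet_windows": ["141", "412", "121", "212", "126", "262", "620", "201", "013", "131", "313"],
  "triplet_classes": ["forward_polling", "unclassified", "backwards_polling", "unclassified", "unclassified", "right_scenery", "unclassified", "unclassified", "unclassified", "guidance", "guidance"],
  "total_windows": [10],
  "singletons": [10]
}
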