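# Default northern/southern locality classification used by the origin
# tests. Localities absent from both lists are unassigned and excluded.
northern: [1, 20, 21, 22, 23, 25, 26, 35, 36, 37, 38, 39]
southern: [2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 18,
           27, 28, 29, 30, 31, 32, 33, 34, 40, 41, 42, 43, 44, 45, 46]
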