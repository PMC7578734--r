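study_id,acupoint
S01,BL14
S01,HT5
S01,LU6
S01,LU9
S01,PC6
S01,RN17
S02,HT5
S02,LI11
S02,LU6
S02,LU9
S02,PC6
S02,RN4
S03,BL20
S03,HT5
S03,LR3
S03,LU6
S03,LU9
S03,PC6
S04,BL17
S04,HT5
S04,KI3
S04,LU6
S04,LU9
S04,PC6
S05,LU6
S05,LU9
S05,PC6
S05,SP6
S05,ST40
S06,HT5
S06,PC6
S06,RN14
S06,RN6
S07,BL14
S07,BL15
S07,BL17
S07,LU9
S07,PC6
S08,BL15
S08,LI11
S08,LR3
S08,LU9
S08,PC6
S09,BL15
S09,LU9
S09,PC6
S09,RN17
S09,ST40
S10,BL15
S10,LU9
S10,PC4
S10,PC6
S10,RN4
S11,BL14
S11,BL23
S11,HT7
S11,LU9
S11,PC6
S12,HT7
S12,LI11
S12,LU9
S12,PC6
S12,SP6
S13,HT7
S13,KI3
S13,LR3
S13,LU9
S13,PC6
S14,BL17
S14,LU9
S14,PC6
S14,ST40
S15,LI4
S15,LU9
S15,PC6
S15,RN17
S16,LU9
S16,PC4
S16,PC6
S16,RN4
S17,BL20
S17,LU9
S17,RN6
S18,BL14
S18,BL15
S18,PC6
S18,RN14
S18,ST36
S19,BL15
S19,HT3
S19,LI11
S19,PC6
S19,ST36
S20,BL15
S20,HT4
S20,LR3
S20,PC6
S20,ST36
S21,BL17
S21,HT7
S21,PC2
S21,PC6
S21,ST36
S22,HT7
S22,PC3
S22,PC6
S22,ST36
S22,ST40
S23,HT7
S23,PC6
S23,PC7
S23,RN17
S23,ST36
S24,BL23
S24,PC6
S24,SP10
S24,SP8
S24,ST36
S25,BL13
S25,LU1
S25,PC6
S25,SP9
S25,ST36
S26,HT1
S26,HT6
S26,LU7
S26,PC6
S26,RN12
S27,ST36
S27,Xiongtong
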