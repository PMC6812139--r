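# Worked-example prostate cohort: clinical metadata (tab-delimited).
# 32 cancers (C1-C32), 16 normal (N1-N16) and 9 benign-disease (B1-B9) tissues.
# gleason_grade is the reported predominant grade of the specimen and is kept
# separate from the score decomposition (primary+secondary); it is the field
# grade groups are derived from. Grades for C5-C7 are reconciled from the
# subgroup denominators of the source summary tables (blank in the published
# matrix); all other values are as published. Missing M with stated N0 is
# treated as M0 downstream.
tissue_id	tissue_class	gleason_score	gleason_primary	gleason_secondary	gleason_grade	tnm	risk_reported
C1	cancer	 9	 4	 5	4	T3N0M1	high
C2	cancer	 9	 5	 4	4-5	T2N1M1c	high
C3	cancer	 9	 5	 4	5	T3aN0M0	high
C4	cancer	 8	 4	 4	4	T3N0M0	high
C5	cancer	 9	 4	 5	4	T2N0M0	high
C6	cancer	 9	 4	 5	4	T2N0M0	high
C7	cancer	 9	 4	 5	4	T2N0M0	high
C8	cancer	 8	 4	 4	4	Unknown	high
C9	cancer	 7	 3	 4	4	T3N0M1b	high
C10	cancer	 7	 3	 4	3	T4N1M1c	high
C11	cancer	 7	NA	NA	3	T3N0	high
C12	cancer	 7	NA	NA	3	T2N0	intermediate
C13	cancer	 7	NA	NA	3	T2N0	intermediate
C14	cancer	 7	 3	 4	NA	T2N0M0	intermediate
C15	cancer	 7	 3	 4	4	T2N0M0	intermediate
C16	cancer	 7	 3	 4	4	T2N0M0	intermediate
C17	cancer	 7	 3	 4	NA	T1N0M0	intermediate
C18	cancer	 7	NA	NA	NA	T2N0	intermediate
C19	cancer	 7	NA	NA	NA	T2N0	intermediate
C20	cancer	 4	 2	 2	2	T4N1M1	high
C21	cancer	 3	 1	 2	2	T3N1M1	high
C22	cancer	 6	 2	 4	4	T3N0M1b	high
C23	cancer	 6	 3	 3	3	T3N1M0	high
C24	cancer	 6	 3	 3	3	T3N0M0	high
C25	cancer	 6	 3	 3	3	T2N0M0	low
C26	cancer	 6	 3	 3	3	T2N0M0	low
C27	cancer	 6	NA	NA	NA	T2N0	low
C28	cancer	 5	 1	 4	NA	T2N0M0	low
C29	cancer	 5	 2	 3	3	T2N0M0	low
C30	cancer	 5	 2	 3	3	T2N0M0	low
C31	cancer	 4	 2	 2	2	T2N0M0	low
C32	cancer	 3	 1	 2	1	T1N0M0	low
N1	normal	NA	NA	NA	NA	NA	NA
N2	normal	NA	NA	NA	NA	NA	NA
N3	normal	NA	NA	NA	NA	NA	NA
N4	normal	NA	NA	NA	NA	NA	NA
N5	normal	NA	NA	NA	NA	NA	NA
N6	normal	NA	NA	NA	NA	NA	NA
N7	normal	NA	NA	NA	NA	NA	NA
N8	normal	NA	NA	NA	NA	NA	NA
N9	normal	NA	NA	NA	NA	NA	NA
N10	normal	NA	NA	NA	NA	NA	NA
N11	normal	NA	NA	NA	NA	NA	NA
N12	normal	NA	NA	NA	NA	NA	NA
N13	normal	NA	NA	NA	NA	NA	NA
N14	normal	NA	NA	NA	NA	NA	NA
N15	normal	NA	NA	NA	NA	NA	NA
N16	normal	NA	NA	NA	NA	NA	NA
B1	benign_disease	NA	NA	NA	NA	NA	NA
B2	benign_disease	NA	NA	NA	NA	NA	NA
B3	benign_disease	NA	NA	NA	NA	NA	NA
B4	benign_disease	NA	NA	NA	NA	NA	NA
B5	benign_disease	NA	NA	NA	NA	NA	NA
B6	benign_disease	NA	NA	NA	NA	NA	NA
B7	benign_disease	NA	NA	NA	NA	NA	NA
B8	benign_disease	NA	NA	NA	NA	NA	NA
B9	benign_disease	NA	NA	NA	NA	NA	NA
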