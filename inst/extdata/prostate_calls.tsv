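# Worked-example prostate cohort: per-gene repositioning calls vs the pooled
# normal reference (tab-delimited). One row per ASSAYED (tissue, gene) pair;
# absent pair = not assayed. call: NS = not significant, I = more internal,
# P = more peripheral (KS test, p < 0.01).
# The assay matrix is reconciled from the per-subgroup denominators of the
# published summary tables; where two tissues were interchangeable the choice
# is arbitrary but frozen (C30 unassayed for SP100/SATB1; C32 assayed only
# for SP100; C31 the LMNA GG1/2 slot; benign-disease fills B2/B4/B5(/B6/B9)).
tissue_id	gene	call
C1	SP100	I
C2	SP100	NS
C3	SP100	NS
C4	SP100	I
C5	SP100	NS
C6	SP100	P
C7	SP100	NS
C8	SP100	NS
C10	SP100	NS
C11	SP100	NS
C12	SP100	NS
C13	SP100	NS
C14	SP100	NS
C15	SP100	I
C16	SP100	I
C17	SP100	I
C20	SP100	P
C21	SP100	P
C22	SP100	NS
C23	SP100	NS
C24	SP100	P
C25	SP100	P
C26	SP100	P
C28	SP100	P
C29	SP100	NS
C31	SP100	NS
C32	SP100	NS
N1	SP100	NS
N2	SP100	NS
N6	SP100	NS
N7	SP100	NS
N8	SP100	NS
N9	SP100	NS
N10	SP100	NS
B1	SP100	I
B2	SP100	NS
B3	SP100	I
B4	SP100	NS
B5	SP100	NS
C1	TGFB3	NS
C3	TGFB3	NS
C4	TGFB3	NS
C5	TGFB3	NS
C6	TGFB3	I
C7	TGFB3	I
C8	TGFB3	P
C9	TGFB3	NS
C10	TGFB3	NS
C14	TGFB3	I
C15	TGFB3	NS
C16	TGFB3	NS
C20	TGFB3	NS
C21	TGFB3	P
C23	TGFB3	NS
C24	TGFB3	NS
C25	TGFB3	P
C26	TGFB3	P
C27	TGFB3	NS
C29	TGFB3	NS
C30	TGFB3	NS
C31	TGFB3	NS
N3	TGFB3	P
N4	TGFB3	NS
N6	TGFB3	NS
N7	TGFB3	NS
N11	TGFB3	NS
N12	TGFB3	NS
N13	TGFB3	NS
N14	TGFB3	NS
B2	TGFB3	NS
B4	TGFB3	NS
B5	TGFB3	NS
B6	TGFB3	NS
B9	TGFB3	NS
C3	SATB1	I
C4	SATB1	NS
C5	SATB1	NS
C6	SATB1	P
C7	SATB1	NS
C8	SATB1	P
C9	SATB1	NS
C10	SATB1	NS
C11	SATB1	I
C12	SATB1	NS
C13	SATB1	NS
C14	SATB1	P
C15	SATB1	I
C18	SATB1	NS
C19	SATB1	NS
C20	SATB1	I
C21	SATB1	NS
C22	SATB1	NS
C23	SATB1	NS
C25	SATB1	NS
C26	SATB1	NS
C29	SATB1	NS
C31	SATB1	I
N1	SATB1	NS
N2	SATB1	P
N6	SATB1	NS
N7	SATB1	NS
N8	SATB1	NS
N9	SATB1	NS
N10	SATB1	NS
B2	SATB1	NS
B4	SATB1	NS
B5	SATB1	NS
B6	SATB1	NS
B9	SATB1	NS
C2	LMNA	NS
C5	LMNA	I
C11	LMNA	I
C18	LMNA	NS
C19	LMNA	NS
C20	LMNA	NS
C21	LMNA	NS
C22	LMNA	NS
C26	LMNA	I
C28	LMNA	I
C31	LMNA	NS
N5	LMNA	NS
N6	LMNA	NS
N7	LMNA	NS
N10	LMNA	NS
N15	LMNA	NS
N16	LMNA	NS
B3	LMNA	I
B7	LMNA	NS
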