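# B73 x Zea diploperennis F2 population: regrowth phenotype (R/NR), PCR marker
# genotypes at gt1/tb1/id1 (1 = homozygous Zd allele, 2 = homozygous maize allele,
# 3 = heterozygous, NA = missing), and GBS inclusion flag (TRUE for the 83 plants
# genotyped by sequencing: 46 regrowth, 37 non-regrowth).
plant	phenotype	gt1	tb1	id1	gbs_included
BZ2-006-9	R	1	1	2	TRUE
BZ2-009-6	R	1	1	2	TRUE
BZ2-006-10	R	1	3	2	TRUE
BZ2-009-7	NR	1	NA	2	TRUE
BZ2-001-1	R	1	3	2	FALSE
BZ2-006-11	NR	3	2	2	FALSE
BZ2-009-8	NR	3	2	2	TRUE
BZ2-001-2	R	3	3	1	FALSE
BZ2-006-12	NR	3	3	2	TRUE
BZ2-009-9	R	3	1	2	TRUE
BZ2-001-3	R	1	3	2	FALSE
BZ2-006-13	NR	3	2	1	FALSE
BZ2-009-10	NR	1	3	2	TRUE
BZ2-001-4	R	1	3	2	FALSE
BZ2-006-14	R	3	2	2	TRUE
BZ2-009-11	R	1	3	2	FALSE
BZ2-001-5	R	1	1	2	TRUE
BZ2-007-1	NR	3	2	2	TRUE
BZ2-009-12	R	3	3	2	TRUE
BZ2-002-1	NR	1	3	2	FALSE
BZ2-007-2	NR	3	2	2	FALSE
BZ2-010-1	R	3	2	2	TRUE
BZ2-002-2	NR	1	2	2	FALSE
BZ2-007-3	R	1	2	2	TRUE
BZ2-010-2	NR	NA	3	2	TRUE
BZ2-002-3	R	3	3	2	FALSE
BZ2-007-4	R	3	2	2	FALSE
BZ2-010-3	R	3	1	2	TRUE
BZ2-002-4	R	3	2	1	FALSE
BZ2-007-5	R	3	3	2	TRUE
BZ2-010-4	R	3	2	1	FALSE
BZ2-002-5	NR	3	3	2	FALSE
BZ2-007-6	NR	3	3	2	TRUE
BZ2-010-5	NR	3	1	2	TRUE
BZ2-002-6	NR	3	2	2	FALSE
BZ2-007-7	R	1	3	2	TRUE
BZ2-010-6	R	3	2	2	TRUE
BZ2-002-7	NR	3	2	2	TRUE
BZ2-007-8	R	3	1	2	FALSE
BZ2-010-7	NR	3	1	2	TRUE
BZ2-002-8	R	1	NA	2	FALSE
BZ2-007-9	R	3	1	2	FALSE
BZ2-010-8	R	3	2	2	TRUE
BZ2-002-9	R	3	2	2	TRUE
BZ2-007-10	NR	1	3	2	TRUE
BZ2-010-9	R	1	3	2	TRUE
BZ2-002-10	R	3	3	2	TRUE
BZ2-007-11	NR	3	1	2	FALSE
BZ2-010-10	R	3	2	2	TRUE
BZ2-002-11	NR	1	2	1	TRUE
BZ2-007-12	R	1	2	2	TRUE
BZ2-010-11	R	2	3	2	TRUE
BZ2-002-12	R	1	2	2	FALSE
BZ2-007-13	R	3	1	2	TRUE
BZ2-010-12	NR	2	3	2	TRUE
BZ2-002-13	R	3	3	2	FALSE
BZ2-007-14	NR	1	3	2	TRUE
BZ2-010-13	R	3	3	2	TRUE
BZ2-002-14	NR	1	1	2	FALSE
BZ2-007-15	NR	3	1	2	FALSE
BZ2-010-14	R	1	2	2	FALSE
BZ2-002-15	R	1	3	1	FALSE
BZ2-007-16	R	1	3	2	TRUE
BZ2-010-15	NR	3	3	2	TRUE
BZ2-002-16	R	3	3	1	FALSE
BZ2-007-17	NR	1	NA	1	TRUE
BZ2-010-16	NR	1	3	2	TRUE
BZ2-002-17	NR	3	2	2	TRUE
BZ2-007-18	R	1	1	2	TRUE
BZ2-010-17	R	1	3	2	FALSE
BZ2-002-18	R	1	2	2	TRUE
BZ2-007-19	R	3	2	2	TRUE
BZ2-010-18	NR	3	3	2	TRUE
BZ2-002-19	R	1	2	2	FALSE
BZ2-007-20	R	3	2	2	TRUE
BZ2-010-19	R	2	2	1	TRUE
BZ2-002-20	R	1	2	2	FALSE
BZ2-007-21	NR	3	2	2	TRUE
BZ2-010-20	NR	1	2	1	TRUE
BZ2-002-21	R	1	2	1	TRUE
BZ2-008-1	R	1	1	2	FALSE
BZ2-010-21	NR	3	3	2	FALSE
BZ2-002-22	R	3	2	2	TRUE
BZ2-008-2	R	3	1	2	TRUE
BZ2-011-1	NR	1	NA	1	FALSE
BZ2-002-23	R	3	2	1	TRUE
BZ2-008-3	R	3	1	2	FALSE
BZ2-011-2	R	3	2	2	TRUE
BZ2-002-24	R	3	2	2	FALSE
BZ2-008-4	NR	3	2	2	FALSE
BZ2-011-3	R	2	3	2	FALSE
BZ2-002-25	NR	1	2	2	FALSE
BZ2-008-5	R	3	3	2	TRUE
BZ2-011-4	R	3	1	2	TRUE
BZ2-004-1	R	3	1	2	FALSE
BZ2-008-6	NR	3	2	2	TRUE
BZ2-011-5	R	1	NA	1	FALSE
BZ2-004-2	R	1	3	2	FALSE
BZ2-008-7	NR	3	3	2	TRUE
BZ2-011-6	NR	3	2	2	TRUE
BZ2-004-3	NR	3	2	2	TRUE
BZ2-008-8	R	3	2	2	TRUE
BZ2-011-7	NR	1	2	2	TRUE
BZ2-004-4	R	1	3	2	FALSE
BZ2-008-9	NR	3	2	2	TRUE
BZ2-011-8	NR	2	1	1	TRUE
BZ2-004-5	R	3	2	2	TRUE
BZ2-008-10	R	1	1	2	TRUE
BZ2-011-9	R	3	2	2	TRUE
BZ2-004-6	R	3	1	2	TRUE
BZ2-008-11	NR	3	2	2	TRUE
BZ2-011-10	R	3	1	2	FALSE
BZ2-006-1	NR	3	1	2	TRUE
BZ2-008-12	R	3	3	2	TRUE
BZ2-011-11	R	1	2	2	FALSE
BZ2-006-2	NR	1	1	2	FALSE
BZ2-008-13	R	1	2	2	TRUE
BZ2-011-12	R	1	3	2	TRUE
BZ2-006-3	R	3	3	2	FALSE
BZ2-008-14	NR	1	3	2	TRUE
BZ2-011-13	R	3	1	2	TRUE
BZ2-006-4	R	3	2	2	FALSE
BZ2-009-1	NR	3	3	2	TRUE
BZ2-011-14	NR	3	1	2	TRUE
BZ2-006-5	R	3	3	2	FALSE
BZ2-009-2	R	1	3	1	FALSE
BZ2-011-15	NR	3	3	2	FALSE
BZ2-006-6	NR	3	3	2	TRUE
BZ2-009-3	NR	3	2	2	TRUE
BZ2-011-16	NR	1	2	2	TRUE
BZ2-006-7	R	3	1	2	TRUE
BZ2-009-4	R	1	3	2	TRUE
BZ2-006-8	R	3	1	2	FALSE
BZ2-009-5	NR	3	3	2	TRUE
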