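# Zea diploperennis x Z. mays cv. Rhee Flint derivatives: regrowth phenotype per
# plant. generation F2 = ZR2 intercross family; F3 families each descend from a
# single regrowth F2 plant.
plant	generation	family	phenotype
ZR2-001-1	F2	ZR2-001	R
ZR2-001-59	F2	ZR2-001	R
ZR2-001-116	F2	ZR2-001	R
ZR2-001-168	F2	ZR2-001	NR
ZR2-001-2	F2	ZR2-001	NR
ZR2-001-60	F2	ZR2-001	R
ZR2-001-117	F2	ZR2-001	R
ZR2-001-169	F2	ZR2-001	NR
ZR2-001-3	F2	ZR2-001	R
ZR2-001-62	F2	ZR2-001	R
ZR2-001-118	F2	ZR2-001	NR
ZR2-001-171	F2	ZR2-001	R
ZR2-001-4	F2	ZR2-001	NR
ZR2-001-63	F2	ZR2-001	R
ZR2-001-119	F2	ZR2-001	R
ZR3-003-1	F3	ZR3-003	R
ZR2-001-5	F2	ZR2-001	R
ZR2-001-64	F2	ZR2-001	R
ZR2-001-120	F2	ZR2-001	R
ZR3-003-2	F3	ZR3-003	R
ZR2-001-6	F2	ZR2-001	R
ZR2-001-65	F2	ZR2-001	R
ZR2-001-121	F2	ZR2-001	NR
ZR3-003-3	F3	ZR3-003	R
ZR2-001-7	F2	ZR2-001	NR
ZR2-001-67	F2	ZR2-001	NR
ZR2-001-122	F2	ZR2-001	R
ZR3-003-4	F3	ZR3-003	NR
ZR2-001-9	F2	ZR2-001	R
ZR2-001-68	F2	ZR2-001	NR
ZR2-001-123	F2	ZR2-001	NR
ZR3-003-6	F3	ZR3-003	R
ZR2-001-10	F2	ZR2-001	NR
ZR2-001-69	F2	ZR2-001	NR
ZR2-001-124	F2	ZR2-001	R
ZR3-003-7	F3	ZR3-003	R
ZR2-001-11	F2	ZR2-001	R
ZR2-001-71	F2	ZR2-001	R
ZR2-001-125	F2	ZR2-001	R
ZR3-003-8	F3	ZR3-003	R
ZR2-001-12	F2	ZR2-001	R
ZR2-001-72	F2	ZR2-001	NR
ZR2-001-126	F2	ZR2-001	NR
ZR3-003-9	F3	ZR3-003	R
ZR2-001-13	F2	ZR2-001	NR
ZR2-001-73	F2	ZR2-001	R
ZR2-001-127	F2	ZR2-001	NR
ZR3-003-10	F3	ZR3-003	R
ZR2-001-14	F2	ZR2-001	NR
ZR2-001-74	F2	ZR2-001	R
ZR2-001-128	F2	ZR2-001	NR
ZR3-003-11	F3	ZR3-003	NR
ZR2-001-15	F2	ZR2-001	R
ZR2-001-75	F2	ZR2-001	R
ZR2-001-129	F2	ZR2-001	R
ZR3-003-12	F3	ZR3-003	R
ZR2-001-16	F2	ZR2-001	NR
ZR2-001-77	F2	ZR2-001	NR
ZR2-001-130	F2	ZR2-001	NR
ZR3-003-13	F3	ZR3-003	R
ZR2-001-17	F2	ZR2-001	R
ZR2-001-78	F2	ZR2-001	NR
ZR2-001-131	F2	ZR2-001	NR
ZR3-003-14	F3	ZR3-003	R
ZR2-001-18	F2	ZR2-001	NR
ZR2-001-79	F2	ZR2-001	R
ZR2-001-132	F2	ZR2-001	NR
ZR3-003-15	F3	ZR3-003	R
ZR2-001-19	F2	ZR2-001	NR
ZR2-001-80	F2	ZR2-001	R
ZR2-001-133	F2	ZR2-001	R
ZR3-003-16	F3	ZR3-003	NR
ZR2-001-20	F2	ZR2-001	R
ZR2-001-81	F2	ZR2-001	R
ZR2-001-134	F2	ZR2-001	R
ZR3-005-1	F3	ZR3-005	R
ZR2-001-21	F2	ZR2-001	NR
ZR2-001-82	F2	ZR2-001	NR
ZR2-001-135	F2	ZR2-001	NR
ZR3-005-2	F3	ZR3-005	R
ZR2-001-22	F2	ZR2-001	NR
ZR2-001-83	F2	ZR2-001	NR
ZR2-001-136	F2	ZR2-001	NR
ZR3-005-3	F3	ZR3-005	NR
ZR2-001-23	F2	ZR2-001	R
ZR2-001-84	F2	ZR2-001	R
ZR2-001-137	F2	ZR2-001	R
ZR3-005-4	F3	ZR3-005	NR
ZR2-001-24	F2	ZR2-001	R
ZR2-001-85	F2	ZR2-001	R
ZR2-001-138	F2	ZR2-001	R
ZR3-005-5	F3	ZR3-005	R
ZR2-001-25	F2	ZR2-001	NR
ZR2-001-86	F2	ZR2-001	R
ZR2-001-139	F2	ZR2-001	R
ZR3-005-6	F3	ZR3-005	R
ZR2-001-26	F2	ZR2-001	R
ZR2-001-87	F2	ZR2-001	NR
ZR2-001-140	F2	ZR2-001	NR
ZR3-005-7	F3	ZR3-005	R
ZR2-001-27	F2	ZR2-001	NR
ZR2-001-88	F2	ZR2-001	NR
ZR2-001-141	F2	ZR2-001	R
ZR3-005-8	F3	ZR3-005	R
ZR2-001-28	F2	ZR2-001	NR
ZR2-001-89	F2	ZR2-001	NR
ZR2-001-142	F2	ZR2-001	R
ZR3-005-9	F3	ZR3-005	R
ZR2-001-30	F2	ZR2-001	R
ZR2-001-90	F2	ZR2-001	R
ZR2-001-143	F2	ZR2-001	R
ZR3-005-10	F3	ZR3-005	R
ZR2-001-31	F2	ZR2-001	R
ZR2-001-91	F2	ZR2-001	R
ZR2-001-144	F2	ZR2-001	NR
ZR3-005-11	F3	ZR3-005	NR
ZR20-01-32	F2	ZR2-001	R
ZR2-001-92	F2	ZR2-001	R
ZR2-001-145	F2	ZR2-001	R
ZR3-005-12	F3	ZR3-005	NR
ZR2-001-33	F2	ZR2-001	NR
ZR2-001-93	F2	ZR2-001	R
ZR2-001-146	F2	ZR2-001	R
ZR3-005-13	F3	ZR3-005	R
ZR2-001-34	F2	ZR2-001	R
ZR2-001-94	F2	ZR2-001	NR
ZR2-001-147	F2	ZR2-001	R
ZR3-005-14	F3	ZR3-005	NR
ZR2-001-35	F2	ZR2-001	NR
ZR2-001-95	F2	ZR2-001	NR
ZR2-001-148	F2	ZR2-001	R
ZR3-005-15	F3	ZR3-005	NR
ZR2-001-36	F2	ZR2-001	NR
ZR2-001-97	F2	ZR2-001	R
ZR2-001-149	F2	ZR2-001	R
ZR3-005-16	F3	ZR3-005	NR
ZR2-001-37	F2	ZR2-001	NR
ZR2-001-98	F2	ZR2-001	R
ZR2-001-150	F2	ZR2-001	R
ZR3-009-1	F3	ZR3-009	R
ZR2-001-38	F2	ZR2-001	NR
ZR2-001-99	F2	ZR2-001	R
ZR2-001-151	F2	ZR2-001	R
ZR3-009-2	F3	ZR3-009	R
ZR2-001-39	F2	ZR2-001	R
ZR2-001-100	F2	ZR2-001	R
ZR2-001-152	F2	ZR2-001	NR
ZR3-009-3	F3	ZR3-009	R
ZR2-001-40	F2	ZR2-001	NR
ZR2-001-101	F2	ZR2-001	R
ZR2-001-153	F2	ZR2-001	R
ZR3-009-4	F3	ZR3-009	R
ZR2-001-42	F2	ZR2-001	NR
ZR2-001-102	F2	ZR2-001	R
ZR2-001-154	F2	ZR2-001	R
ZR3-009-5	F3	ZR3-009	R
ZR2-001-43	F2	ZR2-001	R
ZR2-001-103	F2	ZR2-001	R
ZR2-001-155	F2	ZR2-001	NR
ZR3-009-6	F3	ZR3-009	NR
ZR2-001-44	F2	ZR2-001	R
ZR2-001-104	F2	ZR2-001	R
ZR2-001-156	F2	ZR2-001	R
ZR3-009-7	F3	ZR3-009	R
ZR2-001-45	F2	ZR2-001	R
ZR2-001-105	F2	ZR2-001	R
ZR2-001-157	F2	ZR2-001	NR
ZR3-009-8	F3	ZR3-009	R
ZR2-001-47	F2	ZR2-001	NR
ZR2-001-106	F2	ZR2-001	R
ZR2-001-158	F2	ZR2-001	NR
ZR3-009-9	F3	ZR3-009	R
ZR2-001-48	F2	ZR2-001	NR
ZR2-001-107	F2	ZR2-001	NR
ZR2-001-159	F2	ZR2-001	NR
ZR3-009-10	F3	ZR3-009	R
ZR2-001-49	F2	ZR2-001	R
ZR2-001-108	F2	ZR2-001	NR
ZR2-001-160	F2	ZR2-001	R
ZR3-009-11	F3	ZR3-009	R
ZR2-001-51	F2	ZR2-001	NR
ZR2-001-109	F2	ZR2-001	NR
ZR2-001-161	F2	ZR2-001	R
ZR3-009-12	F3	ZR3-009	R
ZR2-001-53	F2	ZR2-001	NR
ZR2-001-110	F2	ZR2-001	R
ZR2-001-162	F2	ZR2-001	NR
ZR3-009-13	F3	ZR3-009	R
ZR2-001-54	F2	ZR2-001	R
ZR2-001-111	F2	ZR2-001	NR
ZR2-001-163	F2	ZR2-001	R
ZR3-009-14	F3	ZR3-009	NR
ZR2-001-55	F2	ZR2-001	R
ZR2-001-112	F2	ZR2-001	R
ZR2-001-164	F2	ZR2-001	R
ZR3-009-15	F3	ZR3-009	NR
ZR2-001-56	F2	ZR2-001	R
ZR2-001-113	F2	ZR2-001	NR
ZR2-001-165	F2	ZR2-001	NR
ZR3-009-16	F3	ZR3-009	R
ZR2-001-57	F2	ZR2-001	R
ZR2-001-114	F2	ZR2-001	NR
ZR2-001-166	F2	ZR2-001	R
ZR2-001-58	F2	ZR2-001	NR
ZR2-001-115	F2	ZR2-001	NR
ZR2-001-167	F2	ZR2-001	NR
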