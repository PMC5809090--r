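cell_id	rank	or_name	per_million	clade_printed	fold_bound_printed	weak_predominance
s18928	1	or106-8	14123	A	78	FALSE
s18928	2	or109-4	180	A	78	FALSE
s18928	3	or109-7	16	A	78	FALSE
s18930	1	or111-11	55	A	21	FALSE
s18930	2	or106-8	2	A	21	FALSE
s20545	1	or107-1	3835	A	1000	FALSE
s20566	1	or106-11	8655	A	5500	FALSE
s20566	2	or125-4	1	A	5500	FALSE
s20599	1	or106-8	9160	A	1.5	TRUE
s20599	2	or111-2	5172	A	1.5	TRUE
s20599	3	or111-11	685	A	1.5	TRUE
s20599	4	or110-2	299	A	1.5	TRUE
s23546	1	or112-1	12914	A	6700	FALSE
s23546	2	or103-1	2	A	6700	FALSE
s23554	1	or106-3	1647	A	270	FALSE
s23554	2	or106-2	6	A	270	FALSE
s23554	3	or132-5	2	A	270	FALSE
s23563	1	or112-1	14853	A	5500	FALSE
s23563	2	or111-3	2	A	5500	FALSE
s23563	3	or103-4	1	A	5500	FALSE
s23563	4	or128-10	1	A	5500	FALSE
s23574	1	or111-4	11205	A	6	FALSE
s23574	2	or111-11	1770	A	6	FALSE
s23574	3	or111-6	1579	A	6	FALSE
s23574	4	or111-3	4	A	6	FALSE
s18927	1	or121-2p	5768	B	600	FALSE
s18927	2	or111-11	9	B	600	FALSE
s18927	3	or106-8	4	B	600	FALSE
s20556	1	or125-4	5153	B	30	FALSE
s20556	2	or133-8	144	B	30	FALSE
s20556	3	or106-7	49	B	30	FALSE
s20556	4	or133-7	5	B	30	FALSE
s20565	1	or115-5	1037	B	1000	FALSE
s23547	1	or128-10	10143	B	2800	FALSE
s23547	2	or112-1	3	B	2800	FALSE
s23547	3	or132-5	2	B	2800	FALSE
s23547	4	zgc:152857/119-1	1	B	2800	FALSE
s23551	1	or125-4	24371	B	6900	FALSE
s23551	2	or112-1	3	B	6900	FALSE
s23552	1	zgc:152857/119-1	31586	B	30000	FALSE
s23552	2	or119-2	1	B	30000	FALSE
s23555	1	or125-5	8376	B	40	FALSE
s23555	2	or125-7	207	B	40	FALSE
s23555	3	or125-6	8	B	40	FALSE
s23555	4	or125-3	1	B	40	FALSE
s23557	1	or119-2	6548	B	1300	FALSE
s23557	2	or132-5	5	B	1300	FALSE
s23567	1	or115-12	98	B	70	FALSE
s23567	2	or133-2	1	B	70	FALSE
s23570	1	or116-1	706	B	200	FALSE
s23570	2	or111-4	3	B	200	FALSE
s23570	3	or133-2	1	B	200	FALSE
s18931	1	or130-1	154	C	40	FALSE
s18931	2	or106-8	3	C	40	FALSE
s20544	1	or129-1	3190	C	1000	FALSE
s20595	1	or136-1	10114	C	14	FALSE
s20595	2	or106-7	676	C	14	FALSE
s20595	3	or133-1	2	C	14	FALSE
s20595	4	or125-4	2	C	14	FALSE
s20595	5	or106-8	1	C	14	FALSE
s23549	1	or129-1	3483	C	3000	FALSE
s23550	1	or136-1	788	C	700	FALSE
s23558	1	or133-2	2126	C	1	TRUE
s23558	2	or129-1	1747	C	1	TRUE
s23558	3	or112-1	2	C	1	TRUE
s23558	4	or132-5	1	C	1	TRUE
s23559	1	or132-5	31328	C	2100	FALSE
s23559	2	or132-4	1	C	2100	FALSE
s23560	1	or134-1	773	C	160	FALSE
s23560	2	or132-5	5	C	160	FALSE
s23560	3	or112-1	1	C	160	FALSE
s23571	1	or133-2	20600	C	2280	FALSE
s23571	2	or133-1	9	C	2280	FALSE
s23571	3	or133-5	1	C	2280	FALSE
s23572	1	or129-1	1162	C	530	FALSE
s23572	2	or133-2	2	C	530	FALSE
s23572	3	or111-4	1	C	530	FALSE
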