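species	stripes	l1	l2	lr	L	height	SL	max_size	n_hosts
syn_sp01	3	0.7658	0.4431	0.7908	2.014	3.231	8.481	6	4
syn_sp02	3	0.731	0.4527	0.7787	2.0576	2.694	6.425	6.9	6
syn_sp03	3	0.6723	0.406	0.5958	1.8456	4.754	9.008	14.8	9
syn_sp04	2	0.5879	0.4232	0.7074	1.9234	3.641	10.214	11.6	9
syn_sp05	2	NA	NA	NA	NA	NA	NA	18.4	3
syn_sp06	2	0.5712	0.4512	0.7531	2.0509	4.35	10.193	10.5	1
syn_sp07	2	0.5861	0.4409	0.6983	2.0039	5.629	11.579	7.7	7
syn_sp08	2	0.6362	0.4702	0.7643	2.1372	3.651	9.48	14	5
syn_sp09	0	0.2638	0.4082	0.601	1.8556	2.955	6.96	14.3	10
syn_sp10	1	NA	NA	NA	NA	NA	NA	8.6	2
syn_sp11	1	0.4425	0.5229	0.7281	2.3768	3.646	7.862	12.7	7
syn_sp12	1	0.3885	0.4295	0.7458	1.9523	5.387	12.192	10	1
syn_sp13	1	0.3561	0.3751	0.5782	1.7051	5.155	10.059	10.9	6
syn_sp14	2	0.523	0.4606	0.7739	2.0936	4.042	8.815	12.6	10
syn_sp15	2	0.4996	0.4347	0.7385	1.9758	4.051	8.264	5	9
syn_sp16	3	0.5071	0.3793	0.6935	1.7243	4.233	10.55	17.6	6
syn_sp17	3	0.5898	0.4277	0.7444	1.9442	3.252	7.586	7.5	1
syn_sp18	3	0.5601	0.4799	0.907	2.1813	3.853	7.799	12.4	9
syn_sp19	3	0.7986	0.5641	0.8222	2.5643	3.811	10.43	11.6	4
syn_sp20	2	0.365	0.4292	0.695	1.9508	3.011	6.872	5.3	10
syn_sp21	2	NA	NA	NA	NA	NA	NA	17	3
syn_sp22	3	NA	NA	NA	NA	NA	NA	14.9	2
syn_sp23	2	0.394	0.3663	0.6387	1.6652	4.778	10.663	8.4	7
syn_sp24	3	0.7294	0.4168	0.6118	1.8947	3.991	8.329	17.4	6
syn_sp25	2	NA	NA	NA	NA	NA	NA	11.1	9
syn_sp26	1	0.364	0.4498	0.7666	2.0443	6.14	10.602	6.7	9
syn_sp27	3	0.5199	0.3714	0.6359	1.6882	3.127	7.278	10.3	8
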