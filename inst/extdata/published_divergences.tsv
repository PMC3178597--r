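label	n	coi_intra	coi_inter	its_intra	its_inter	source_better	flags
Amanita flavoconia	2	0.0000	0.0930	0.0022	0.0511	COI
Amanita porphyria	2	0.0000	0.1275	0.0000	CAPPED	ITS
Boletus badius	2	0.0000	0.0439	0.0000	CAPPED	ITS
Boletus edulis	9	0.0062	0.0020	0.0104	0.0497	ITS	COI intraspecific >= interspecific
Boletus nobilissimus	4	0.0000	0.0020	0.0039	0.0223	ITS
Boletus regineus	4	0.0041	0.0020	0.0142	0.0096	ITS	COI and ITS intraspecific >= interspecific
Boletus rex-veris	2	0.0020	0.0020	0.0029	0.0308	ITS	COI intraspecific >= interspecific
Boletus variipes	2	0.0000	0.0145	0.0048	0.0538	COI
Catathelasma ventricosa	2	0.0000	0.1055	0.0043	CAPPED	ITS
Clitocybe sp. (143Alg, 38Alg)	2	0.0000	0.0860	0.0091	CAPPED	ITS
Collybia cirrhata	3	0.0000	0.0129	0.0000	0.0345	COI
Entoloma clypeatum	2	0.0000	0.1276	0.0000	CAPPED	ITS
Entoloma sinuatum	2	0.0000	0.0762	0.0028	CAPPED	ITS
Entoloma sp. (parasite on Tricholoma focale)	2	0.0064	0.0417	0.0000	0.0390	ITS
Hygrocybe conica	3	0.0000	0.0260	0.0329	CAPPED	ITS
Hygrocybe lacmus	2	0.0000	0.1201	0.0083	CAPPED	ITS
Hygrocybe miniata	2	0.0064	0.0238	0.0747	CAPPED	ITS	may be two cryptic species
Hygrophorus agathiosmus	2	0.0043	0.0373	0.0000	CAPPED	ITS
Hygrophorus flavodiscus	3	0.0000	0.0283	0.0025	CAPPED	ITS
Hygrophorus pudorinus	3	0.0000	0.0554	0.0056	CAPPED	ITS
Inferiboletus	2	0.0000	0.0335	0.0015	CAPPED	ITS
Laccaria spp.	2	NA	0.0107	NA	0.0575	NA	n spans different species
Lacrymaria/Psathyrella	2	NA	0.0394	NA	0.0837	NA	n spans different species
Leccinum vulpinum	2	0.0000	0.0208	0.0050	CAPPED	ITS	incomplete sequence present; only first 408bp included
Lepiota castanea/Lepiota sp. 16JS06	2	NA	0.0305	NA	0.0313	NA	n spans different species
Pholiota sp.	3	0.0000	0.1051	0.0000	CAPPED	ITS
Pluteus sp.A	4	0.0021	0.0216	0.0000	0.0733	COI
Pluteus sp.B	2	0.0000	0.0043	0.0000	0.0323	ITS
Pluteus sp.C	2	0.0021	0.0043	0.0186	0.0258	COI
Pluteus sp.D	2	0.0000	0.0173	0.0000	0.0258	ITS
Pluteus sp.E	2	0.0000	0.0173	0.0067	0.0390	COI
Psathyrella 72CAT06/151CAT06	2	NA	0.0693	NA	0.1207	NA	n spans different species; incomplete sequence present; first 213 bp excluded
Psathyrella gracilis	2	0.0000	0.0786	0.0022	CAPPED	ITS
Stropharia ambigua	4	0.0000	0.1432	0.0000	CAPPED	ITS
Suillus cavipes	2	0.0000	0.0328	0.0000	0.0662	ITS
Tricholoma inamoenum	3	0.0043	0.0260	0.0000	CAPPED	ITS
Tricholoma sejunctum group	3	NA	0.0107	NA	0.1136	NA	n spans different species
Xerocomus subtomentosus	2	0.0000	0.0271	0.0022	CAPPED	ITS
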