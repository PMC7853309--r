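species	strain	accession	pyrenoid	score
Chloromonas chlorococcoides	SAG 15.82	LC547865	present	-23.6
Chloromonas chlorococcoides	SAG 15.82	LC547866	present	-23.6
Chloromonas chlorococcoides	SAG 15.82	LC547867	present	-23.0
Chloromonas chlorococcoides	SAG 15.82	LC547868	present	-25.9
Chloromonas chlorococcoides	SAG 15.82	LC547869	present	-26.3
Chloromonas chlorococcoides	SAG 12.96	LC547870	present	-25.9
Chloromonas chlorococcoides	SAG 16.82	LC547871	present	-23.6
Chloromonas chlorococcoides	SAG 16.82	LC547872	present	-23.0
Chloromonas chlorococcoides	SAG 16.82	LC547873	present	-26.3
Chloromonas chlorococcoides	SAG 72.81	LC547874	present	-23.6
Chloromonas chlorococcoides	SAG 72.81	LC547875	present	-23.0
Chloromonas difformis	NIES-2215	LC547876	present	-26.6
Chloromonas difformis	NIES-2215	LC547877	present	-29.6
Chloromonas difformis	NIES-2215	LC547878	present	-26.6
Chloromonas typhlos	NIES-2243	LC547879	present	-22.8
Chloromonas typhlos	NIES-2243	LC547880	present	-24.3
Chloromonas typhlos	SAG 26.86	LC547881	present	-22.8
Chloromonas typhlos	SAG 26.86	LC547882	present	-19.6
Chloromonas typhlos	SAG 26.86	LC547883	present	-27.7
Chloromonas typhlos	SAG 26.86	LC547884	present	-27.7
Chloromonas reticulata	SAG 29.83	LC547885	absent	-30.5
Chloromonas reticulata	SAG 29.83	LC547886	absent	-31.2
Chloromonas reticulata	SAG 26.90	LC547887	absent	-31.6
Chloromonas reticulata	SAG 26.90	LC547888	absent	-30.5
Chloromonas reticulata	SAG 26.90	LC547889	absent	-30.5
Chloromonas reticulata	SAG 26.90	LC547890	absent	-31.2
Chloromonas reticulata	SAG 32.86	LC547891	absent	-30.5
Chloromonas reticulata	SAG 32.86	LC547892	absent	-30.5
Chloromonas reticulata	SAG 32.86	LC547893	absent	-31.2
Chloromonas reticulata	SAG 32.86	LC547894	absent	-31.2
Chloromonas rosae	SAG 51.72	LC547895	absent	-31.4
Chloromonas rosae	SAG 51.72	LC547896	absent	-33.6
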