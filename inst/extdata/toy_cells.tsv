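# toy per-cell score table: 12 cells, 4 output classes
cell_id	true_label	score_target	score_background	score_debris	score_out_of_focus
c001	target	0.90	0.05	0.03	0.02
c002	target	0.85	0.10	0.02	0.03
c003	target	0.60	0.30	0.05	0.05
c004	background	0.10	0.80	0.05	0.05
c005	background	0.05	0.85	0.05	0.05
c006	background	0.20	0.70	0.05	0.05
c007	background	0.02	0.90	0.04	0.04
c008	background	0.40	0.50	0.05	0.05
c009	debris	0.10	0.10	0.75	0.05
c010	debris	0.05	0.15	0.70	0.10
c011	out_of_focus	0.10	0.20	0.10	0.60
c012	out_of_focus	0.05	0.15	0.10	0.70
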