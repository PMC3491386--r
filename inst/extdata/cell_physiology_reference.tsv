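# Published morphometry of T. oceanica CCMP1005 under iron-replete (fe_plus)
# and iron-limited (fe_minus) growth: population-mean cylinder dimensions and
# the back-calculated unit-cell ("cellular unit") surface and volume, with
# their reported uncertainties.
condition	mean_diameter_um	mean_length_um	unit_surface_um2	unit_surface_sd	unit_volume_um3	unit_volume_sd	n_cells
fe_plus	5.9	5.5	122	3	100	4	20
fe_minus	4.7	7.0	140	5	80	5	20
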