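name,formula,density_g_cm3,density_min_g_cm3,density_max_g_cm3,n_water_max,density_hydrate_g_cm3,group,note
sodium carbonate,Na2CO3,2.54,,,10,1.44,natron,anhydrate to decahydrate (natron main phase)
nahcolite,NaHCO3,2.21,,,0,,natron,sodium bicarbonate
halite,NaCl,2.17,,,0,,natron,sodium chloride
sodium sulphate,Na2SO4,2.664,,,10,1.464,natron,anhydrate to decahydrate (thenardite to mirabilite)
trona,Na2CO3.NaHCO3.2H2O,2.14,2.11,2.17,0,,natron,trisodium hydrogendicarbonate dihydrate; default density is the range midpoint
hydroxyapatite,Ca10(PO4)6(OH)2,1.8,,,0,,reference,bone mineral at measured cortical-bone mineral density (not crystal density)
water,H2O,1.0,,,0,,misc,liquid water
aluminium,Al,2.699,,,0,,filter,beam filter
copper,Cu,8.96,,,0,,filter,beam filter
molybdenum,Mo,10.22,,,0,,filter,beam filter
luag,Lu3Al5O12,6.73,,,0,,scintillator,lutetium aluminium garnet
ggg,Gd3Ga5O12,7.08,,,0,,scintillator,gadolinium gallium garnet
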