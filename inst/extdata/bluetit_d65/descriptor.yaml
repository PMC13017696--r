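# Packaged default viewer: tetrachromatic passerine ("blue tit type").
# The sensitivity curves are SYNTHETIC: pigment-template (nomogram) alpha+beta
# bands at the blue tit single-cone peak absorbances, filtered by simplified
# sigmoidal oil-droplet and ocular-media transmission. They approximate, but
# are not, measured whole-eye tables; load your own directory to match a
# specific published viewer.
name: bluetit_d65
sensitivities: sensitivities_synthetic_nomogram.csv
single_cones: [UVS, SWS, MWS, LWS]
double_cone: DBL
abundances: [1.0, 1.92, 2.68, 2.7]
weber_ref: 0.05
weber_double: 0.05
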