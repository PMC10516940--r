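# per-variant allele counts for the toy panel (synthetic, ~23% target pool)
variant_id	ref_count	alt_count
snv1	770	230
snv2	765	235
snv3	772	228
snv4	768	232
snv5	775	225
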