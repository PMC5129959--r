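id	direction
miR-760	up_miliary
novel-miR-1003	up_miliary
novel-miR-2508	up_miliary
miR-1254	up_non_miliary
novel-miR-804	up_non_miliary
novel-miR-1628	up_non_miliary
novel-miR-1927	up_non_miliary
novel-miR-2353	up_non_miliary
novel-miR-2916	up_non_miliary
novel-miR-3475	up_non_miliary
novel-miR-3784	up_non_miliary
piRno_hsa_009295	up_non_miliary
novel-piR-n9_chr19_12817301	up_non_miliary
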