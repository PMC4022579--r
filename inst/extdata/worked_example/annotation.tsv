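sample_id	compound	class_label	dosing_time	vehicle	is_control	control_group_id
GC01_r1	GC01	GC	7	CO	FALSE	ctrl
GC01_r2	GC01	GC	7	CO	FALSE	ctrl
GC01_r3	GC01	GC	7	CO	FALSE	ctrl
GC02_r1	GC02	GC	7	CO	FALSE	ctrl
GC02_r2	GC02	GC	7	CO	FALSE	ctrl
GC02_r3	GC02	GC	7	CO	FALSE	ctrl
NGC01_r1	NGC01	NGC	7	CO	FALSE	ctrl
NGC01_r2	NGC01	NGC	7	CO	FALSE	ctrl
NGC01_r3	NGC01	NGC	7	CO	FALSE	ctrl
NGC02_r1	NGC02	NGC	7	CO	FALSE	ctrl
NGC02_r2	NGC02	NGC	7	CO	FALSE	ctrl
NGC02_r3	NGC02	NGC	7	CO	FALSE	ctrl
NC01_r1	NC01	NC	7	CO	FALSE	ctrl
NC01_r2	NC01	NC	7	CO	FALSE	ctrl
NC01_r3	NC01	NC	7	CO	FALSE	ctrl
NC02_r1	NC02	NC	7	CO	FALSE	ctrl
NC02_r2	NC02	NC	7	CO	FALSE	ctrl
NC02_r3	NC02	NC	7	CO	FALSE	ctrl
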