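# Maps canonical field names to the column headers used in a cohort file.
id: id
group: group
ab42_plasma: ab42_plasma
ab40_plasma: ab40_plasma
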