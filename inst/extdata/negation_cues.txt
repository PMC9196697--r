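# Negation cue dictionary, one cue per line; multi-word cues allowed.
not
no
without
except
other than
free of
absence of
absent
exclude
excluding
excluded
neither
nor
denies
denial of
lack of
lacking
never
rather than
with the exception of
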