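# Open-nomenclature qualifiers stripped during name cleaning.
# One token per line; matching is case-insensitive and a trailing period
# is optional ("cf" matches "cf."). Everything after the first matched
# token is dropped, since the following epithet is an uncertain
# identification.
aff.
cf.
cff.
sp.
spp.
nr.
prope
gr.
s.l.
s.s.
indet.
?
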