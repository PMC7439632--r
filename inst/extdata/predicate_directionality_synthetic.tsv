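# Predicate directionality reference table (47 predicates: 35 directed, 12 undirected).
# The undirected entries follow an expert consensus assessment of protein-protein
# predicates; the directed predicate names are a SYNTHETIC reconstruction of a
# typical standardized biomedical predicate vocabulary (the original directed list
# is proprietary).  Negated predicates carry the category of their base predicate.
# columns: predicate<TAB>category
binds with	undirected
coexists with	undirected
does not coexist with	undirected
forms protein complex with	undirected
interacts with	undirected
does not interact with	undirected
is associated with	undirected
is compared with	undirected
is functionally related to	undirected
is spatially related to	undirected
is the same as	undirected
ortholog is associated with	undirected
inhibits	directed
does not inhibit	directed
stimulates	directed
does not stimulate	directed
activates	directed
catalysis precedes	directed
precedes	directed
controls expression of	directed
controls phosphorylation of	directed
controls state change of	directed
controls transport of	directed
converts	directed
cleaves	directed
degrades	directed
phosphorylates	directed
dephosphorylates	directed
ubiquitinates	directed
methylates	directed
acetylates	directed
transports	directed
regulates	directed
positively regulates	directed
negatively regulates	directed
causes	directed
affects	directed
does not affect	directed
augments	directed
disrupts	directed
produces	directed
is upstream of	directed
acts on	directed
represses	directed
induces	directed
modifies	directed
processes	directed
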