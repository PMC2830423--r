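# Binding-dependency rule set for the small-subunit (SSU, 30S) ribosomal
# proteins: the 14 universally conserved proteins plus the four
# bacteria-specific proteins (S6, S16, S18, S20) that other universal
# proteins depend on for binding.
#
# Transcribed from the published 30S assembly map (Nomura-type, as refined
# by kinetic binding-dependency studies), restricted to the stronger,
# non-redundant dependencies. S21 is a terminal protein with no dependents
# and is omitted entirely. S6, S16, S18 and S20 are carried in the ordering
# but excluded from usage averaging: they are absent from Archaea and
# Eukarya (likely non-orthologous displacement or loss), so universally
# conserved positions cannot be called for them.
#
# This rule set admits ~7.3e9 permitted linear evolutionary orders, far too
# many for exhaustive enumeration; position probabilities are compiled from
# random samples (or by the exact subset dynamic programme).
@subunit SSU
@exclude S6 S16 S18 S20
S4:
S7:
S8:
S15:
S17:
S20:
S16: S4 S20
S12: S4 S17
S5: S8 S16
S6: S15
S18: S6 S15
S9: S7
S13: S7
S19: S7 S9
S10: S9
S11: S18
S3: S5 S10
S2: S3
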