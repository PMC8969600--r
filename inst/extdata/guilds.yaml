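# Guild definitions: taxonomy patterns matched against lineage strings.
# This file mirrors default_guilds() and can be edited to redefine guilds.
methane_cycling_archaea:
  - {rank: genus, taxon: Methanolinea}
  - {rank: genus, taxon: Methanosaeta}
  - {rank: genus, taxon: ANME-3}
  - {rank: genus, taxon: Methanoregula}
  - {rank: family, taxon: Methanomicrobiaceae}
srb:
  - {rank: family, taxon: Desulfarculaceae}
  - {rank: family, taxon: Desulfobacteraceae}
  - {rank: family, taxon: Desulfobulbaceae}
  - {rank: family, taxon: Syntrophobacteraceae}
  - {rank: genus, taxon: Desulfatiglans}
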