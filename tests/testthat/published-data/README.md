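# Published-data inputs (not redistributable)

The published-data acceptance check needs inputs that cannot ship with
the package. To run it, place here:

- `5ev6.pdb` — the crystal structure of the free metallo-beta-lactamase
  (PDB entry 5EV6; chain A is used), from the PDB.
- `1ddk.pdb` — the earlier crystal structure used as the counterfactual
  fitting reference (PDB entry 1DDK).
- `<site>_<tag>_<metal>.npc` — the published backbone-amide 1H PCS
  tables measured for the tagged mutants, one file per mutant/tag/lanthanoid combination (for example
  `A53C_C2_Tb.npc`), in the whitespace NPC format
  `residue_number atom_name value error`.

Without these files the corresponding test fails with a pointer to this
README; all other tests are self-contained.
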