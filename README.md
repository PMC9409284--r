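# pyrenav

A desk-scale R toolkit for the structural analysis of pyrethroid
insecticide binding to insect voltage-gated sodium channels, and for
interpreting knockdown-resistance (kdr) mutations against the two
pyrethroid receptor sites, PyR1 (domain II/III interface) and PyR2 (domain
I/II interface).

Pyrethroids prolong sodium-channel opening; resistance arises largely from
channel mutations. Interpreting those mutations needs structure-level
plumbing that this package provides as testable components:

* **Universal residue labels** for P-loop channels (`2k11` = domain II,
  S4-S5 linker helix, position 11; segments `k`/`o`/`p`/`i`), parsing of the
  dual notation `M918/2k11`, and anchored mapping between native numbering
  schemes and labels (`parse_label()`, `assign_labels()`,
  `translate_numbering()`).
* **Structure I/O and superposition**: PDB/mmCIF reading, state-tagged PDB
  writing, and Kabsch superposition on the conserved P1 helices
  (`read_structure()`, `superpose()`, `rmsd_subset()`).
* **A reduced molecular-mechanics model** (united-atom Lennard-Jones,
  distance-dependent-dielectric Coulomb, saturating 10-12 hydrogen bonds,
  a directional halogen-bond term, torsions, positional restraints) with
  derivative-free local minimization and Monte Carlo minimization in
  internal coordinates (`energy()`, `local_minimize()`, `mc_minimize()`).
* **Multi-start docking** with random starting poses, per-pose Monte Carlo
  minimization, a 5 kcal/mol energy window above the apparent global
  minimum, and selection of the pose contacting the most known
  pyrethroid-sensing residues (`dock_ligand()`, `filter_window()`,
  `select_by_sensing_contacts()`).
* **Targeted state transformations**: stepwise driving of selected C-alpha
  atoms toward template positions with relaxation at every step — pore
  opening/inactivation and voltage-sensor deactivation, with bound ligands
  carried along (`morph()`, `deactivate_vsm()`).
* **Interaction analysis**: 4 A contacts, hydrogen/halogen bonds, salt
  bridges, residue environments, and contact gain/loss between gating
  states (`ligand_contacts()`, `contact_diff()`, `residue_environment()`).
* **The kdr mutation atlas**: a machine-readable transcription of the four
  curated mutation tables with per-label PyR1/PyR2 site membership and
  structure-aware mutation reports (`load_kdr_atlas()`, `classify_site()`,
  `mutation_report()`).
* **Synthetic fixtures**: a four-domain mini-channel with two gating
  states, planted sensing residues, toy Type I/II ligands and a verified
  planted docking truth (`make_mini_channel()`, `make_toy_ligand()`,
  `make_docking_truth()`).

## Worked example

```r
library(pyrenav)

## the atlas and the universal nomenclature
atlas <- load_kdr_atlas()
parse_label("M918/2k11")$label
#> <universal_label> M2k11
classify_site("2k11", atlas)
#> [1] "PyR1"
classify_site("1k11", atlas)
#> [1] "PyR2"

## mapping the house fly numbering through the packaged anchors
lm <- assign_labels(c(918L, 1014L, 929L), housefly_annotation())
lm$label
#> [1] "2k11" "2i16" "2o10"

## a synthetic two-state channel with a planted pocket ligand
mc <- make_mini_channel()
mc$open
#> <channel_structure> 740 atoms, 176 residues, state: open_pm
rmsd_subset(mc$open, mc$inactivated, "p1-ca")   # P1 shared exactly
#> [1] 0

## dock the toy Type II ligand into the planted site
site <- site_definition(mc$open, mc$info$sensing, name = "PyR1")
dk <- dock_ligand(mc$open, mc$info$ligand, site,
                  config = docking_config(n_starts = 200, seed = 1))
round(dk$ensemble$energy[1], 1)       # best interaction energy, kcal/mol
length(dk$filtered)                   # poses within the 5 kcal/mol window
dk$selected$contact_labels            # sensing residues the selected pose touches

## inactivate the pore with the ligand bound and diff the contacts
tg <- build_targets(mc$open, mc$inactivated,
                    atom_selection(segment = c("i", "k")))
tj <- morph(mc$open, tg, morph_schedule(n_steps = 10),
            ligands = list(list(ligand = mc$info$ligand,
                                xyz = dk$selected$pose)))
tj$rmsd_to_target[11]                 # 0: converged onto the template
d <- contact_diff(interaction_report(mc$open, dk$selected$pose, mc$info$ligand),
                  interaction_report(tj$structures[[11]],
                                     tj$ligands[[1]]$xyz, mc$info$ligand))
d$lost$label                          # contacts lost upon inactivation
```

The docking numbers are stochastic (seeded); the contact-loss table is the
qualitative signature of the state-dependent action: contacts on the
linker helices and the inner-helix cytoplasmic halves weaken or vanish when
the pore closes, which is why the ligand prefers the open state.

See `vignettes/pyrenav-methods.Rmd` for the model, its parameters and the
design decisions.

## Command line

A thin wrapper over the package functions covers the common entry points:

```sh
Rscript inst/scripts/channeltool.R simulate --out fixtures/ --seed 7
Rscript inst/scripts/channeltool.R label --structure fixtures/channel_open.pdb \
    --annotation fixtures/annotation.tsv --out map.tsv
Rscript inst/scripts/channeltool.R classify --label 2k11
```
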