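#!/usr/bin/env Rscript

# Build the synthetic stand-ins for the three EGFR mutant-inhibitor MD
# runs. Real production trajectories (10 ns, 5000 frames per complex)
# were never deposited, so each complex is emulated by a generated
# trajectory over a kinase-domain-like topology (residues 697 onward,
# deletion mutants missing their deleted stretch) whose per-residue
# fluctuation amplitude near T790 encodes the relationship under study:
# the delE746_A750-like complex is generated least stable around T790,
# the L858R-like complex most stable. Fixtures are written in the
# package's canonical JSON+CSV format for the downstream scripts.

suppressPackageStartupMessages(library(resiflex))

out_dir <- "scratch/trajectories"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

complexes <- list(
  delE746_A750 = list(gaps = 746:750, sigma_near = 0.55),
  delS752_I759 = list(gaps = 752:759, sigma_near = 0.45),
  L858R        = list(gaps = integer(0), sigma_near = 0.35)
)

for (label in names(complexes)) {
  cx <- complexes[[label]]
  recipe <- trajectory_recipe(
    n_residues = 120, atoms_per_residue = 6,
    residue_number_start = 697L, deletion_gaps = cx$gaps,
    per_residue_sigma = 0.25,
    rigid_jitter = list(max_rotation_deg = 15, max_translation_A = 3),
    n_frames = 400, seed = match(label, names(complexes)))
  ref <- make_reference(recipe)
  recipe$per_residue_sigma <- near_focal_sigma(
    ref, 790L, n_near = 20, sigma_near = cx$sigma_near, sigma_far = 0.25)
  traj <- generate_trajectory(ref, recipe)
  write_fixture(traj, file.path(out_dir, label))
  message(sprintf(
    "%s: %d residues (%s), %d frames, sigma %.2f A near T790 / %.2f A elsewhere",
    label, length(unique(traj$topology$residue_number)),
    if (length(cx$gaps)) paste0("missing ", min(cx$gaps), "-", max(cx$gaps))
    else "no deletion",
    n_frames(traj), cx$sigma_near, 0.25))
}
message("fixtures written under ", out_dir)
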