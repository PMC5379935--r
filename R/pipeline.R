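# Orchestration: run the full ring-assembly analysis on a pair of
# structures (a stacked double ring and, optionally, a nucleotide-bound
# complex) and collect one structured report.

#' Analysis configuration
#'
#' @param apo a [structure_model()] or PDB path holding the stacked double
#'   ring (two rings of `n_fold` chains each).
#' @param complex_model optional [structure_model()] or path with bound
#'   nucleotides for the conformational/contact analyses.
#' @param ring_a_chains,ring_b_chains chain identifier vectors of the two
#'   rings; default: first and second half of the apo chains.
#' @param n_fold ring symmetry order (default: length of `ring_a_chains`).
#' @param selection_preset `"CA"` or `"main-chain"` for the RMSD matrix.
#' @param linkage clustering linkage(s) to run.
#' @param rna_resi residue numbers of nucleotides in the complex (default:
#'   residues carrying an O4' atom).
#' @param contact_cutoff protein-RNA contact cutoff, Angstrom.
#' @param anm_gamma,anm_cutoff,anm_modes elastic-network settings.
#' @param sasa_probe probe radius for the buried-surface ensemble.
#' @param z,mass Matthews inputs (copies per cell, Da); used when the apo
#'   model carries a unit cell.
#' @param fp_data optional `fp_dataset` for the binding stage.
#' @param seed recorded in the report; all stages are deterministic given
#'   the inputs.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(apo, complex_model = NULL,
                            ring_a_chains = NULL, ring_b_chains = NULL,
                            n_fold = NULL,
                            selection_preset = c("CA", "main-chain"),
                            linkage = c("complete", "ward"),
                            rna_resi = NULL, contact_cutoff = 3.6,
                            anm_gamma = 1, anm_cutoff = 15, anm_modes = 20,
                            sasa_probe = 1.4, z = NULL, mass = NULL,
                            fp_data = NULL, seed = 1) {
  structure(list(apo = apo, complex_model = complex_model,
                 ring_a_chains = ring_a_chains,
                 ring_b_chains = ring_b_chains, n_fold = n_fold,
                 selection_preset = match.arg(selection_preset),
                 linkage = linkage, rna_resi = rna_resi,
                 contact_cutoff = contact_cutoff, anm_gamma = anm_gamma,
                 anm_cutoff = anm_cutoff, anm_modes = anm_modes,
                 sasa_probe = sasa_probe, z = z, mass = mass,
                 fp_data = fp_data, seed = seed),
            class = "analysis_config")
}

as_model <- function(x) {
  if (inherits(x, "structure_model")) x else read_structure(x)
}

run_stage <- function(report, name, fn) {
  res <- tryCatch(list(ok = TRUE, value = fn()),
                  error = function(e) list(ok = FALSE,
                                           error = conditionMessage(e)))
  report$stages[[name]] <- res
  if (!res$ok) report$failed <- c(report$failed, name)
  report
}

#' Run the full ring-assembly analysis
#'
#' Executes, deterministically for a given configuration: the subunit RMSD
#' matrix with hierarchical clustering (both linkages) and a k = 2 cut, the
#' inter-ring stack geometry, the buried-surface ensemble, the elastic
#' network spectrum with ring counter-rotation overlaps, nucleotide
#' conformation and contact tables (when a complex is supplied), the
#' Matthews block (when a cell and Z/mass are available), and a binding-fit
#' comparison (when titration data are supplied). Stage failures are
#' recorded in the report instead of aborting the remaining stages.
#'
#' @param config an [analysis_config()].
#' @return a `ringstack_report`: list with `config`, `stages` (each stage a
#'   list with `ok` and `value` or `error`) and `failed` (names of failed
#'   stages, empty when all passed).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  report <- list(config = config, stages = list(), failed = character(0))
  apo <- as_model(config$apo)
  chains <- unique(apo$atoms$chain[!apo$atoms$het])
  ring_a <- config$ring_a_chains %||% chains[seq_len(length(chains) %/% 2)]
  ring_b <- config$ring_b_chains %||%
    setdiff(chains, chains[seq_len(length(chains) %/% 2)])
  n_fold <- config$n_fold %||% length(ring_a)
  sel <- atom_selection(preset = config$selection_preset)

  report <- run_stage(report, "rmsd_clustering", function() {
    per_chain <- chain_models(select_atoms(apo, class = "polymer"))
    dm <- rmsd_matrix(per_chain, sel)
    trees <- lapply(config$linkage, function(lk) hierarchical_cluster(dm, lk))
    names(trees) <- config$linkage
    cuts <- lapply(trees, cut_tree, k = 2)
    list(distance_matrix = dm,
         mean_rmsd = mean(dm$d[upper.tri(dm$d)]),
         trees = trees, k2 = cuts,
         edges = similarity_edges(dm, levels = 2))
  })

  report <- run_stage(report, "stack_geometry", function() {
    stack_geometry(select_atoms(apo, chains = ring_a, class = "polymer"),
                   select_atoms(apo, chains = ring_b, class = "polymer"),
                   n_fold = n_fold)
  })

  report <- run_stage(report, "buried_surface", function() {
    buried_surface_area(apo,
                        atom_selection(chains = ring_a, class = "polymer"),
                        atom_selection(chains = ring_b, class = "polymer"),
                        ensemble = default_bsa_ensemble(config$sasa_probe))
  })

  report <- run_stage(report, "anm", function() {
    anm <- build_anm(apo, gamma = config$anm_gamma,
                     cutoff = config$anm_cutoff)
    ca <- suppressWarnings(select_atoms(apo, atom_selection(preset = "CA")))
    if (n_atoms(ca) == 0) ca <- apo
    ia <- which(ca$atoms$chain %in% ring_a)
    ib <- which(ca$atoms$chain %in% ring_b)
    ov <- ring_rotation_overlap(anm, ia, ib, axis = c(0, 0, 1),
                                k = config$anm_modes)
    list(anm = anm, n_zero = anm$n_zero,
         eigenvalues = anm$eigenvalues[anm$n_zero +
                                         seq_len(min(config$anm_modes,
                                                     3 * nrow(anm$nodes) -
                                                       anm$n_zero))],
         counter_rotation = ov,
         max_overlap = max(ov$overlap))
  })

  if (!is.null(config$complex_model)) {
    cplx <- as_model(config$complex_model)
    # nucleotides are recognised by their furanose O4' atom
    nuc <- unique(cplx$atoms[cplx$atoms$name == "O4'",
                             c("chain", "resi"), drop = FALSE])
    if (!is.null(config$rna_resi))
      nuc <- nuc[nuc$resi %in% config$rna_resi, , drop = FALSE]
    report <- run_stage(report, "nucleotides", function() {
      rows <- lapply(seq_len(nrow(nuc)), function(i) {
        at <- cplx$atoms
        nt <- structure_model(at[at$resi == nuc$resi[i] &
                                   at$chain == nuc$chain[i], , drop = FALSE])
        ch <- glycosidic_chi(nt)
        pk <- pseudorotation(nt)
        data.frame(chain = nuc$chain[i], resi = nuc$resi[i],
                   chi = ch$chi, conformer = ch$conformer,
                   P = pk$P, nu_max = pk$nu_max,
                   pucker_class = pk$pucker_class,
                   hemisphere = pk$hemisphere, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    report <- run_stage(report, "contacts", function() {
      rna_chains <- unique(nuc$chain)
      prot_chains <- setdiff(unique(cplx$atoms$chain[!cplx$atoms$het]),
                             rna_chains)
      contact_table(cplx,
                    atom_selection(chains = prot_chains, class = "polymer"),
                    atom_selection(chains = rna_chains),
                    cutoff = config$contact_cutoff)
    })
  }

  if (!is.null(apo$cell) && !is.null(config$z) && !is.null(config$mass)) {
    report <- run_stage(report, "matthews", function()
      matthews(apo$cell, config$z, config$mass))
  }

  if (!is.null(config$fp_data)) {
    report <- run_stage(report, "binding", function() {
      fl <- fit_model(config$fp_data, "logistic4")
      fd <- fit_model(config$fp_data, "depletion")
      list(logistic = fl, depletion = fd, comparison = compare_fits(fl, fd))
    })
  }

  class(report) <- "ringstack_report"
  report
}

#' @export
print.ringstack_report <- function(x, ...) {
  cat("ringstack report:", length(x$stages), "stage(s)\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-18s %s\n", nm,
                if (x$stages[[nm]]$ok) "ok"
                else paste("FAILED:", x$stages[[nm]]$error)))
  invisible(x)
}
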