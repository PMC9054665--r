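#' Full-analysis configuration
#'
#' Bundles the inputs and tuning parameters of a complete promoter-motif
#' analysis run: the promoter universe, the motifs, the analysis window, the
#' gene sets, the profile settings, and the statistical parameters.
#'
#' @param universe A [promoter_universe].
#' @param gene_sets Named list of [gene_set] objects (matched or not; they
#'   are (re-)matched against the universe at run time).
#' @param motifs List of [motif_spec]s; default [standard_motifs()].
#' @param window Analysis window for counting/presence/GC content; default
#'   `c(-140, -41)` (the proximal promoter).
#' @param profile_windows Integer vector of profile window sizes; default
#'   `c(6, 100)`.
#' @param profile_region Region for coarse profiles; default `c(-500, 50)`.
#' @param n_perm Permutations for count comparisons; default 9999.
#' @param fdr_level FDR level used by summaries; default 0.05.
#' @param seed Integer seed for the permutation tests.
#' @return Object of class `run_config`.
#' @export
run_config <- function(universe, gene_sets, motifs = standard_motifs(),
                       window = c(-140L, -41L), profile_windows = c(6L, 100L),
                       profile_region = c(-500L, 50L), n_perm = 9999L,
                       fdr_level = 0.05, seed = 1L) {
  stopifnot(inherits(universe, "promoter_universe"),
            is.list(gene_sets), length(gene_sets) >= 1L,
            all(vapply(gene_sets, inherits, logical(1), "gene_set")),
            is.list(motifs), length(motifs) >= 1L,
            all(vapply(motifs, inherits, logical(1), "motif_spec")))
  window <- check_window(window, region(universe))
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- vapply(gene_sets, `[[`, character(1), "name")
  }
  structure(list(universe = universe, gene_sets = gene_sets, motifs = motifs,
                 window = window, profile_windows = as.integer(profile_windows),
                 profile_region = as.integer(profile_region),
                 n_perm = check_int(n_perm, "n_perm"),
                 fdr_level = fdr_level, seed = check_int(seed, "seed")),
            class = "run_config")
}

#' Over-representation analysis for every motif and gene set
#'
#' For each motif: summarise the universe in the analysis window, match every
#' gene set, and build the enrichment table with BH correction applied within
#' that motif's family of sets.
#'
#' @param config A [run_config].
#' @return `data.frame` with a `motif` column prepended to the
#'   [enrich_gene_sets()] columns, one row per (motif, set).
#' @export
run_enrichment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- lapply(config$motifs, function(mo) {
    summ <- summarize_genes(config$universe, mo, config$window)
    sets <- lapply(config$gene_sets, match_gene_set, universe = config$universe)
    for (gs in sets) {
      if (length(gs$matched) == 0L) {
        stop(sprintf("gene set '%s' matches no universe gene", gs$name),
             call. = FALSE)
      }
    }
    tab <- enrich_gene_sets(summ, sets)
    cbind(motif = mo$name, as.data.frame(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Positional profiles for every motif and gene group
#'
#' One genes-with-hit track per (motif, group), with the full universe
#' included as the control group, at each configured window size.
#'
#' @param config A [run_config].
#' @return Named list (by motif name) of named lists (by group name,
#'   including `"ALL"`) of named lists (by window size, e.g. `"w100"`) of
#'   [motif_profile] tracks.
#' @export
run_profiles <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sets <- lapply(config$gene_sets, match_gene_set, universe = config$universe)
  groups <- c(list(ALL = NULL), lapply(sets, `[[`, "matched"))
  out <- lapply(config$motifs, function(mo) {
    lapply(groups, function(genes) {
      tracks <- lapply(config$profile_windows, function(ws) {
        reg <- config$profile_region
        if (ws == nchar(mo$pattern)) {
          motif_profile(config$universe, mo, ws, profile_region = reg,
                        mode = "per_position_occurrence", genes = genes)
        } else {
          motif_profile(config$universe, mo, ws, profile_region = reg,
                        mode = "genes_with_hit", genes = genes)
        }
      })
      names(tracks) <- paste0("w", config$profile_windows)
      tracks
    })
  })
  names(out) <- vapply(config$motifs, `[[`, character(1), "name")
  out
}

#' Group-versus-background comparisons of motif counts and GC content
#'
#' For each motif and each gene set: a permutation test on per-gene in-window
#' motif counts restricted to motif-containing genes (group vs the universe's
#' motif-containing genes), and a Welch's t test on in-window GC content (all
#' matched genes vs the whole universe). BH correction is applied across the
#' gene sets, separately for each motif and test type.
#'
#' @param config A [run_config].
#' @return `data.frame`, one row per (motif, set, test) with columns `motif`,
#'   `set`, `test` ("permutation_counts" / "welch_gc"), `group_n`,
#'   `background_n`, `statistic`, `p_value`, `p_adj`, `seed`, `n_perm`.
#' @export
run_group_comparisons <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- list()
  for (mo in config$motifs) {
    summ <- summarize_genes(config$universe, mo, config$window)
    sets <- lapply(config$gene_sets, match_gene_set, universe = config$universe)
    bg_counts <- summ$n_occurrences[summ$has_motif]
    perm_rows <- lapply(seq_along(sets), function(i) {
      gs <- sets[[i]]
      idx <- match(gs$matched, summ$gene_id)
      grp <- summ$n_occurrences[idx][summ$has_motif[idx]]
      if (length(grp) == 0L) {
        return(data.frame(motif = mo$name, set = gs$name,
                          test = "permutation_counts", group_n = 0L,
                          background_n = length(bg_counts), statistic = NA_real_,
                          p_value = NA_real_, p_adj = NA_real_,
                          seed = config$seed, n_perm = config$n_perm,
                          stringsAsFactors = FALSE))
      }
      pt <- permutation_test(grp, bg_counts, n_perm = config$n_perm,
                             seed = config$seed + i)
      data.frame(motif = mo$name, set = gs$name, test = "permutation_counts",
                 group_n = pt$group_size, background_n = pt$background_size,
                 statistic = pt$observed, p_value = pt$p_value,
                 p_adj = NA_real_, seed = pt$seed, n_perm = pt$n_perm,
                 stringsAsFactors = FALSE)
    })
    welch_rows <- lapply(sets, function(gs) {
      idx <- match(gs$matched, summ$gene_id)
      wt <- welch_t(summ$gc_content[idx], summ$gc_content)
      data.frame(motif = mo$name, set = gs$name, test = "welch_gc",
                 group_n = length(idx), background_n = nrow(summ),
                 statistic = wt$t, p_value = wt$p_value, p_adj = NA_real_,
                 seed = NA_integer_, n_perm = NA_integer_,
                 stringsAsFactors = FALSE)
    })
    perm <- do.call(rbind, perm_rows)
    ok <- !is.na(perm$p_value)
    perm$p_adj[ok] <- bh_adjust(perm$p_value[ok])
    welch <- do.call(rbind, welch_rows)
    welch$p_adj <- bh_adjust(welch$p_value)
    res[[mo$name]] <- rbind(perm, welch)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline and write its tables and tracks
#'
#' Orchestrates [run_enrichment()], [run_group_comparisons()] and
#' [run_profiles()] and writes deterministic TSV outputs plus a structured
#' metadata sidecar (package version, seed, parameters) to `out_dir`. Outputs
#' are pure functions of (inputs, config, seed): re-running with the same
#' triple reproduces the files byte for byte.
#'
#' @param config A [run_config].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with elements `enrichment`, `comparisons`,
#'   `profiles`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  enr <- run_enrichment(config)
  cmp <- run_group_comparisons(config)
  prof <- run_profiles(config)
  write_track(enr, file.path(out_dir, "enrichment.tsv"))
  write_track(cmp, file.path(out_dir, "comparisons.tsv"))
  for (mo in names(prof)) {
    for (grp in names(prof[[mo]])) {
      for (w in names(prof[[mo]][[grp]])) {
        fn <- sprintf("profile_%s_%s_%s.tsv",
                      gsub("[^A-Za-z0-9]", "", mo),
                      gsub("[^A-Za-z0-9]", "_", grp), w)
        write_track(prof[[mo]][[grp]][[w]], file.path(out_dir, fn))
      }
    }
  }
  meta <- c(sprintf("package_version\t%s",
                    as.character(utils::packageVersion("promotif"))),
            sprintf("seed\t%d", config$seed),
            sprintf("n_perm\t%d", config$n_perm),
            sprintf("window\t%d\t%d", config$window[1L], config$window[2L]),
            sprintf("region\t%d\t%d", region(config$universe)[1L],
                    region(config$universe)[2L]),
            sprintf("n_genes\t%d", length(config$universe)),
            sprintf("fdr_level\t%g", config$fdr_level),
            sprintf("motifs\t%s",
                    paste(vapply(config$motifs, `[[`, character(1), "pattern"),
                          collapse = ",")))
  writeLines(meta, file.path(out_dir, "run_metadata.tsv"))
  invisible(list(enrichment = enr, comparisons = cmp, profiles = prof))
}
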