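## End-to-end orchestration: ingest -> annotate -> site statistics ->
## cross-dataset clustering -> terminus consistency, with artifact writing,
## a hashed manifest, and report assembly.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the pooled truncation analysis
#'
#' Executes the full pipeline on a set of proteoform identification datasets
#' against one canonical database: record filtering, canonical placement and
#' truncation-state assignment, per-dataset site statistics and diagnostics,
#' the cross-dataset normalized-frequency feature matrix with missingness
#' filtering and Ward clustering, and cross-dataset terminus consistency with
#' annotation categories.
#'
#' @param datasets named list of proteoform record data.frames (e.g. from
#'   [read_proteoform_table()] or [generate_dataset()]).
#' @param db a `papt_db` canonical database.
#' @param k number of clusters at which the dendrogram is cut.
#' @param missing_threshold missingness fraction for
#'   [filter_by_missingness()].
#' @param near_window residue window for the `near_annotated` category.
#' @param bin_width length-bin width in residues.
#' @param min_datasets minimal consistency count for reported termini.
#' @param out_dir optional directory; when given, all intermediate artifacts
#'   are written as TSV/JSON together with an md5 manifest.
#' @return list with per-dataset results (`annotated`, `sites`, `summary`,
#'   `nfm`), the `feature_matrix`, `clustering`, `assignments`,
#'   `cluster_summary`, `termini_profiles`, `terminus_calls`, `filter_reports`
#'   and (when written) the `manifest`.
#' @export
run_papt <- function(datasets, db, k = 15L, missing_threshold = 0.40,
                     near_window = 15L, bin_width = 25L, min_datasets = 2L,
                     out_dir = NULL) {
  stopifnot(is.list(datasets), !is.null(names(datasets)),
            !anyDuplicated(names(datasets)), inherits(db, "papt_db"))
  per <- list()
  filter_reports <- list()
  for (id in names(datasets)) {
    per[[id]] <- .stage("ingest", {
      lf <- link_and_filter(datasets[[id]], db)
      filter_reports[[id]] <- lf$report
      lf
    })
  }
  ann <- lapply(names(per), function(id) {
    .stage("annotate", annotate_proteoforms(per[[id]]$records, db))
  })
  names(ann) <- names(per)

  site_res <- lapply(names(ann), function(id) {
    .stage("site_stats", {
      a <- ann[[id]]
      sites <- extract_truncation_sites(a, db)
      bonds <- count_peptide_bonds(a)
      nfm <- list(N = normalized_frequency(count_truncation_events(sites, "N_only"), bonds),
                  C = normalized_frequency(count_truncation_events(sites, "C_only"), bonds))
      summary <- list(
        state = dataset_state_summary(a),
        prsm = prsm_state_summary(a),
        known = known_in_uniprot_fraction(a, db),
        proline_ratio = proline_insource_ratio(sites),
        histograms = terminus_position_histograms(a),
        length_bins = length_bin_state_proportions(a, bin_width)
      )
      list(sites = sites, bonds = bonds, nfm = nfm, summary = summary)
    })
  })
  names(site_res) <- names(ann)

  fm <- .stage("meta_cluster", {
    assemble_feature_matrix(lapply(site_res, `[[`, "nfm"))
  })
  fmf <- .stage("meta_cluster", filter_by_missingness(fm, missing_threshold))
  clustering <- .stage("meta_cluster", cluster_truncation_sites(fmf))
  assignments <- .stage("meta_cluster", cut_clusters(clustering, k))
  cluster_summary <- .stage("meta_cluster",
                            cluster_motif_summary(fmf, assignments))

  profiles <- .stage("consistency", build_termini_profiles(ann))
  calls <- .stage("consistency",
                  consistency_counts(profiles, min_datasets, db, near_window))

  res <- list(annotated = ann,
              sites = lapply(site_res, `[[`, "sites"),
              summaries = lapply(site_res, function(x) x$summary),
              nfm = lapply(site_res, `[[`, "nfm"),
              feature_matrix = fmf,
              clustering = clustering,
              assignments = assignments,
              cluster_summary = cluster_summary,
              termini_profiles = profiles,
              terminus_calls = calls,
              filter_reports = filter_reports,
              params = list(k = k, missing_threshold = missing_threshold,
                            near_window = near_window, bin_width = bin_width,
                            min_datasets = min_datasets))
  if (!is.null(out_dir)) {
    res$manifest <- write_artifacts(res, out_dir)
  }
  res
}

nfm_long <- function(nfm_pair) {
  do.call(rbind, lapply(names(nfm_pair), function(sc) {
    m <- nfm_pair[[sc]]
    data.frame(scope = sc,
               x = rep(AA_STANDARD, 20L),
               x_prime = rep(AA_STANDARD, each = 20L),
               value = as.vector(m),
               missing = is.na(as.vector(m)),
               stringsAsFactors = FALSE)
  }))
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, name) {
    p <- file.path(out_dir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    p
  }
  paths <- character(0)
  for (id in names(res$annotated)) {
    paths <- c(paths, wtsv(res$annotated[[id]],
                           paste0("annotated_", id, ".tsv")))
    paths <- c(paths, wtsv(nfm_long(res$nfm[[id]]),
                           paste0("normalized_frequency_", id, ".tsv")))
  }
  fm <- data.frame(site_key = rownames(res$feature_matrix),
                   res$feature_matrix, check.names = FALSE)
  paths <- c(paths, wtsv(fm, "feature_matrix_filtered.tsv"))
  hc <- res$clustering$hclust
  paths <- c(paths, wtsv(data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                                    height = hc$height),
                         "merge_sequence.tsv"))
  paths <- c(paths, wtsv(data.frame(site_key = names(res$assignments),
                                    cluster = unname(res$assignments)),
                         "cluster_assignments.tsv"))
  paths <- c(paths, wtsv(res$cluster_summary, "cluster_summary.tsv"))
  paths <- c(paths, wtsv(res$termini_profiles, "termini_profiles.tsv"))
  paths <- c(paths, wtsv(res$terminus_calls, "terminus_calls.tsv"))
  rp <- file.path(out_dir, "filter_reports.json")
  jsonlite::write_json(res$filter_reports, rp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, rp)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  mp <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Assemble the analysis report
#'
#' Collects the per-dataset state proportions, PrSM means, known-in-database
#' fractions and proline ratios, the filtered feature-matrix dimensions, the
#' cluster summaries and the top consistent termini into one machine-readable
#' structure, optionally written as JSON plus a short human-readable text
#' summary.
#'
#' @param res result of [run_papt()].
#' @param path optional output path (`.json`; a sibling `.txt` summary is
#'   written next to it).
#' @return the report list, invisibly when written.
#' @export
write_report <- function(res, path = NULL) {
  per_dataset <- lapply(res$summaries, function(s) {
    list(state_proportions = as.list(s$state$state_proportions),
         protein_level = as.list(s$state$protein_level),
         prsm_mean = as.list(s$prsm),
         known_fraction = as.list(s$known),
         proline_ratio = as.numeric(s$proline_ratio))
  })
  top <- utils::head(res$terminus_calls, 25L)
  report <- list(
    datasets = per_dataset,
    feature_matrix_dim = dim(res$feature_matrix),
    n_clusters = max(res$assignments),
    cluster_summary = res$cluster_summary,
    top_consistent_termini = top,
    params = res$params
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    txt <- sub("\\.json$", ".txt", path)
    con <- file(txt, "w")
    on.exit(close(con))
    writeLines(c(
      "Pooled analysis of protein truncations - summary",
      sprintf("Datasets: %d", length(per_dataset)),
      sprintf("Filtered feature matrix: %d sites x %d datasets",
              nrow(res$feature_matrix), ncol(res$feature_matrix)),
      sprintf("Clusters: %d", max(res$assignments)),
      "",
      "Per-dataset truncated fraction / proline X' ratio:",
      vapply(names(per_dataset), function(id) {
        s <- per_dataset[[id]]
        sprintf("  %s: %.1f%% truncated, proline ratio %.2f", id,
                100 * (1 - s$state_proportions$FULL_LENGTH),
                s$proline_ratio)
      }, character(1)),
      "",
      "Top consistent noncanonical termini:",
      vapply(seq_len(min(nrow(top), 10L)), function(i) {
        sprintf("  %s %s-terminus at %d: %d datasets (%s)", top$accession[i],
                top$terminus[i], top$position[i], top$n_datasets[i],
                if ("category" %in% names(top)) top$category[i] else "")
      }, character(1))
    ), con)
    return(invisible(report))
  }
  report
}
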