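## Seeded generator of synthetic proteomes and proteoform identification
## lists with ground truth, plus an exact analytic oracle for the expected
## normalized truncation-site frequency under the generative model.

#' Configuration for the synthetic truncation study
#'
#' Bundles every parameter of the generative model: a canonical proteome with
#' planted signal peptides and domains, and per-dataset proteoform sampling
#' with a full-length fraction, start-methionine excision, residue-pair
#' specific cleavage enrichment, signal-peptide cleavage, and an N-terminus
#' only in-source fragmentation process biased toward proline at X'.
#'
#' Cleavage enrichment keys are `"X|Y"` for an exact residue pair, `"X|*"`
#' for all bonds C-terminal to X, and `"*|Y"` for all bonds N-terminal to Y.
#' Wildcards multiply onto the baseline of 1; an exact key overrides both.
#'
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param n_proteins number of canonical proteins.
#' @param length_distribution list `min`, `max`, `meanlog`, `sdlog` of the
#'   (truncated log-normal) protein length distribution, in residues.
#' @param aa_composition 20 probabilities (order [AA_STANDARD]) for residues
#'   after the initiator methionine; `NULL` = uniform 1/20.
#' @param signal_peptide_fraction fraction of proteins with a signal peptide.
#' @param signal_length_range inclusive signal-peptide length range.
#' @param domain_count_range inclusive range of domains per protein.
#' @param domain_length_range inclusive domain length range.
#' @param n_proteoforms proteoform records per dataset.
#' @param full_length_fraction probability a record is full length.
#' @param met_excision_prob probability a full-length record has the
#'   start-methionine excised.
#' @param cleavage_enrichment named multipliers (>= 0) on bond-hydrolysis
#'   cleavage rates; see Details.
#' @param insource_fraction fraction of truncated records produced by
#'   in-source fragmentation (N-terminal-only cuts).
#' @param insource_p_bias weight multiplier for bonds with proline at X'
#'   in the in-source process.
#' @param signal_fraction fraction of truncated records of signal-bearing
#'   proteins produced by signal-peptide cleavage.
#' @param fragment_probs probabilities that a hydrolysis cut yields the
#'   N-side, the C-side, or both fragments (names `N`, `C`, `both`).
#' @param min_fragment_length fragments shorter than this are never emitted
#'   (cut choices are renormalized accordingly), mimicking MS observability.
#' @param prsm_model list `slope`, `truncated_factor` of the geometric-like
#'   PrSM-count model (mean 1 + slope * abundance rank scale, scaled down for
#'   truncated records); `NULL` = no PrSM information.
#' @param abundance_distribution list `meanlog`, `sdlog` of the log-normal
#'   protein abundance distribution.
#' @return classed list of validated parameters (`papt_sim_config`).
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 300L,
                       length_distribution = list(min = 60L, max = 500L,
                                                  meanlog = log(180),
                                                  sdlog = 0.45),
                       aa_composition = NULL,
                       signal_peptide_fraction = 0.25,
                       signal_length_range = c(18L, 29L),
                       domain_count_range = c(0L, 2L),
                       domain_length_range = c(30L, 60L),
                       n_proteoforms = 2000L,
                       full_length_fraction = 0.29,
                       met_excision_prob = 0.5,
                       cleavage_enrichment = c("D|P" = 8, "R|*" = 3, "K|*" = 3),
                       insource_fraction = 0.05,
                       insource_p_bias = 4,
                       signal_fraction = 0.2,
                       fragment_probs = c(N = 0.4, C = 0.4, both = 0.2),
                       min_fragment_length = 5L,
                       prsm_model = list(slope = 20, truncated_factor = 0.25),
                       abundance_distribution = list(meanlog = 3, sdlog = 1.5)) {
  if (is.null(aa_composition)) aa_composition <- rep(1 / 20, 20)
  stopifnot(length(aa_composition) == 20L,
            abs(sum(aa_composition) - 1) < 1e-8,
            all(aa_composition >= 0))
  fracs <- c(signal_peptide_fraction, full_length_fraction, met_excision_prob,
             insource_fraction, signal_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (insource_fraction + signal_fraction > 1) {
    stop("insource_fraction + signal_fraction must not exceed 1")
  }
  if (any(!is.finite(cleavage_enrichment)) || any(cleavage_enrichment < 0)) {
    stop("cleavage multipliers must be finite and non-negative")
  }
  fragment_probs <- fragment_probs / sum(fragment_probs)
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 length_distribution = length_distribution,
                 aa_composition = aa_composition,
                 signal_peptide_fraction = signal_peptide_fraction,
                 signal_length_range = as.integer(signal_length_range),
                 domain_count_range = as.integer(domain_count_range),
                 domain_length_range = as.integer(domain_length_range),
                 n_proteoforms = as.integer(n_proteoforms),
                 full_length_fraction = full_length_fraction,
                 met_excision_prob = met_excision_prob,
                 cleavage_enrichment = cleavage_enrichment,
                 insource_fraction = insource_fraction,
                 insource_p_bias = insource_p_bias,
                 signal_fraction = signal_fraction,
                 fragment_probs = fragment_probs,
                 min_fragment_length = as.integer(min_fragment_length),
                 prsm_model = prsm_model,
                 abundance_distribution = abundance_distribution),
            class = "papt_sim_config")
}

## 20x20 multiplier matrix from the named enrichment vector
cleavage_weight_matrix <- function(enrichment) {
  W <- matrix(1, 20L, 20L, dimnames = list(AA_STANDARD, AA_STANDARD))
  if (length(enrichment) == 0L) return(W)
  keys <- strsplit(names(enrichment), "|", fixed = TRUE)
  exact <- list()
  for (i in seq_along(keys)) {
    x <- keys[[i]][1L]
    y <- keys[[i]][2L]
    if (x == "*" && y != "*") {
      W[, y] <- W[, y] * enrichment[i]
    } else if (y == "*" && x != "*") {
      W[x, ] <- W[x, ] * enrichment[i]
    } else {
      exact[[length(exact) + 1L]] <- c(x, y, enrichment[i])
    }
  }
  for (e in exact) W[e[1L], e[2L]] <- as.numeric(e[3L])
  W
}

#' Generate a synthetic canonical proteome
#'
#' Proteins always start with methionine; residues after it are drawn from
#' the configured composition. Signal peptides (feature begin 1) and
#' non-overlapping domains separated by linkers of at least 5 residues are
#' planted into the annotation features; abundances are log-normal.
#'
#' @param cfg a [sim_config()] object. The configured seed is set before
#'   generation, so repeated calls are identical.
#' @return a `papt_db` with abundances attached; the planted features are the
#'   ground truth.
#' @export
generate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "papt_sim_config"))
  set.seed(cfg$seed)
  ld <- cfg$length_distribution
  if (cfg$domain_count_range[1L] > 0L) {
    need <- cfg$domain_count_range[1L] *
      (cfg$domain_length_range[1L] + 5L) + max(cfg$signal_length_range) + 1L
    if (need > ld$min) stop("infeasible domain layout: domains exceed length")
  }
  n <- cfg$n_proteins
  len <- pmin(pmax(round(rlnorm(n, ld$meanlog, ld$sdlog)), ld$min), ld$max)
  acc <- sprintf("SYN%05d", seq_len(n))
  seqs <- vapply(len, function(L) {
    paste0("M", paste(sample(AA_STANDARD, L - 1L, replace = TRUE,
                             prob = cfg$aa_composition), collapse = ""))
  }, character(1))
  names(seqs) <- acc

  feats <- list()
  has_sig <- runif(n) < cfg$signal_peptide_fraction
  sig_end <- rep(NA_integer_, n)
  sr <- cfg$signal_length_range
  sig_end[has_sig] <- sample(seq(sr[1L], sr[2L]), sum(has_sig), replace = TRUE)
  if (any(has_sig)) {
    feats[[1L]] <- data.frame(accession = acc[has_sig],
                              category = "signal_peptide",
                              begin = 1L, end = sig_end[has_sig],
                              stringsAsFactors = FALSE)
  }
  dr <- cfg$domain_count_range
  dl <- cfg$domain_length_range
  for (i in seq_len(n)) {
    nd <- if (dr[2L] > dr[1L]) sample(seq(dr[1L], dr[2L]), 1L) else dr[1L]
    if (nd == 0L) next
    pos <- if (is.na(sig_end[i])) 2L else sig_end[i] + 2L
    placed <- 0L
    while (placed < nd) {
      w <- sample(seq(dl[1L], dl[2L]), 1L)
      if (pos + w - 1L > len[i] - 1L) break
      feats[[length(feats) + 1L]] <- data.frame(
        accession = acc[i], category = "domain",
        begin = pos, end = pos + w - 1L, stringsAsFactors = FALSE)
      pos <- pos + w + 5L
      placed <- placed + 1L
    }
    if (placed < dr[1L]) stop("infeasible domain layout: domains exceed length")
  }
  features <- if (length(feats)) do.call(rbind, feats) else empty_features()
  ad <- cfg$abundance_distribution
  db <- new_protein_db(seqs, features)
  db$abundance <- setNames(rlnorm(n, ad$meanlog, ad$sdlog), acc)
  db
}

## per-protein bond bookkeeping shared by the generator and the oracle
.bond_info <- function(seq, W, cfg) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  a <- ch[-L]
  b <- ch[-1L]
  nb <- L - 1L
  j <- seq_len(nb)
  w_hyd <- W[cbind(a, b)]
  min_len <- cfg$min_fragment_length
  valid_n <- j >= min_len
  ## a C-side fragment starting at position 2 of a Met-initiated protein is
  ## indistinguishable from the Met-excised full-length form and is not emitted
  valid_c <- (L - j) >= min_len & !(j == 1L & ch[1L] == "M")
  w_ins <- ifelse(b == "P", cfg$insource_p_bias, 1) * ((L - j) >= min_len & j >= 2L)
  list(L = L, a = a, b = b, w_hyd = w_hyd, valid_n = valid_n,
       valid_c = valid_c, w_ins = w_ins)
}

#' Generate one synthetic proteoform identification dataset
#'
#' Proteins are sampled proportionally to abundance. With probability
#' `full_length_fraction` the record is full length (start-Met excised with
#' `met_excision_prob`); otherwise a truncation process is chosen:
#' signal-peptide cleavage (signal-bearing proteins), in-source fragmentation
#' (N-terminal-only cuts, proline-biased at X'), or bond hydrolysis (bond
#' weights follow the cleavage-enrichment multipliers; the cut yields the
#' N-side, C-side or both fragments). PrSM counts increase with protein
#' abundance and are lower for truncated records. Every record carries a
#' ground-truth process label.
#'
#' @param db proteome from [generate_proteome()].
#' @param cfg the [sim_config()] used (or a compatible one).
#' @param dataset_id identifier written into the records.
#' @param seed optional seed for this dataset; when `NULL` the current RNG
#'   stream continues.
#' @return list with `records` (canonical-dialect data.frame) and `truth`
#'   (data.frame with `process` labels and cut coordinates).
#' @export
generate_dataset <- function(db, cfg, dataset_id, seed = NULL) {
  stopifnot(inherits(db, "papt_db"), inherits(cfg, "papt_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  acc <- names(db$sequences)
  np <- length(acc)
  n <- cfg$n_proteoforms
  W <- cleavage_weight_matrix(cfg$cleavage_enrichment)
  sig <- db$features[db$features$category == "signal_peptide", , drop = FALSE]
  sig_end <- setNames(rep(NA_integer_, np), acc)
  sig_end[sig$accession] <- sig$end
  lens <- nchar(db$sequences)

  pick <- sample(acc, n, replace = TRUE, prob = db$abundance)
  L <- lens[pick]
  full <- runif(n) < cfg$full_length_fraction
  process <- rep("hydrolysis", n)
  start <- rep(1L, n)
  end <- as.integer(L)

  mex <- full & runif(n) < cfg$met_excision_prob &
    substr(db$sequences[pick], 1L, 1L) == "M"
  process[full] <- "full_length"
  process[mex] <- "met_excision"
  start[mex] <- 2L

  tr <- which(!full)
  if (length(tr)) {
    p_sig <- ifelse(is.na(sig_end[pick[tr]]), 0, cfg$signal_fraction)
    r <- runif(length(tr))
    proc <- ifelse(r < p_sig, "signal_cleavage",
            ifelse(r < p_sig + cfg$insource_fraction, "insource", "hydrolysis"))
    process[tr] <- proc

    si <- tr[proc == "signal_cleavage"]
    start[si] <- sig_end[pick[si]] + 1L

    ## per-protein cut-bond sampling for the hydrolysis and in-source processes
    extra_list <- list()
    for (a_ in unique(pick[tr[proc != "signal_cleavage"]])) {
      bi <- .bond_info(db$sequences[[a_]], W, cfg)
      pf <- cfg$fragment_probs
      hj <- tr[proc == "hydrolysis" & pick[tr] == a_]
      if (length(hj)) {
        u <- c(bi$w_hyd * pf[["N"]] * bi$valid_n,
               bi$w_hyd * pf[["C"]] * bi$valid_c,
               bi$w_hyd * pf[["both"]] * (bi$valid_n & bi$valid_c))
        if (sum(u) <= 0) stop("no admissible cut bond for protein ", a_)
        drawn <- sample.int(length(u), length(hj), replace = TRUE, prob = u)
        jdx <- (drawn - 1L) %% (bi$L - 1L) + 1L
        sdx <- c("N", "C", "both")[(drawn - 1L) %/% (bi$L - 1L) + 1L]
        ## N-side fragment: 1..j (C-truncated); C-side fragment: j+1..L
        keep_n <- sdx == "N"
        keep_c <- sdx == "C"
        both <- sdx == "both"
        end[hj[keep_n]] <- jdx[keep_n]
        start[hj[keep_c]] <- jdx[keep_c] + 1L
        ## "both" cuts emit two records: keep the C-side here, append N-sides
        start[hj[both]] <- jdx[both] + 1L
        if (any(both)) {
          extra_list[[length(extra_list) + 1L]] <-
            data.frame(pick = a_, start = 1L, end = jdx[both],
                       stringsAsFactors = FALSE)
        }
      }
      ij <- tr[proc == "insource" & pick[tr] == a_]
      if (length(ij)) {
        if (sum(bi$w_ins) <= 0) stop("no admissible in-source bond for ", a_)
        jdx <- sample.int(bi$L - 1L, length(ij), replace = TRUE,
                          prob = bi$w_ins)
        start[ij] <- jdx + 1L
      }
    }
    extra <- if (length(extra_list)) do.call(rbind, extra_list) else NULL
    if (!is.null(extra)) {
      pick <- c(pick, extra$pick)
      start <- c(start, extra$start)
      end <- c(end, as.integer(extra$end))
      process <- c(process, rep("hydrolysis", nrow(extra)))
    }
  }

  sequence <- substr(db$sequences[pick], start, end)
  prsm <- rep(NA_integer_, length(pick))
  if (!is.null(cfg$prsm_model)) {
    rank_scale <- setNames(rank(db$abundance) / np, acc)
    mu <- 1 + cfg$prsm_model$slope * rank_scale[pick]
    truncated <- !(process %in% c("full_length", "met_excision"))
    mu[truncated] <- 1 + (mu[truncated] - 1) * cfg$prsm_model$truncated_factor
    prsm <- rgeom(length(mu), prob = 1 / mu) + 1L
  }
  records <- data.frame(dataset_id = as.character(dataset_id),
                        accession = unname(pick),
                        sequence = unname(sequence),
                        proforma = NA_character_,
                        prsm_count = as.integer(prsm),
                        start = as.integer(unname(start)),
                        end = as.integer(unname(end)),
                        stringsAsFactors = FALSE)
  truth <- data.frame(dataset_id = as.character(dataset_id),
                      accession = unname(pick),
                      process = process,
                      start = as.integer(unname(start)),
                      end = as.integer(unname(end)),
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Expected normalized truncation-site frequency under the generative model
#'
#' Computes, by exact summation over every bond of every protein (weighted by
#' abundance-proportional sampling and the configured process mixture), the
#' expected value of [normalized_frequency()] for a residue pair. This is an
#' independent brute-force calculation over the generative process, including
#' fragment-length rejection, the two-sided fragment emission, the
#' start-methionine-excision site exception, the in-source and
#' signal-cleavage processes, and the full-length contribution to the
#' peptide-bond background.
#'
#' @param db proteome from [generate_proteome()].
#' @param cfg the [sim_config()] describing the generation.
#' @param pair residue pair, either `"D|P"` or `c("D", "P")`.
#' @return expected log2 normalized frequency for the pair (`NA` when the
#'   pair has zero expected bond count); attribute `matrix` carries the full
#'   20x20 expectation.
#' @export
analytic_expected_enrichment <- function(db, cfg, pair) {
  stopifnot(inherits(db, "papt_db"), inherits(cfg, "papt_sim_config"))
  if (length(pair) == 1L) pair <- strsplit(pair, "|", fixed = TRUE)[[1]]
  stopifnot(length(pair) == 2L, all(pair %in% AA_STANDARD))
  W <- cleavage_weight_matrix(cfg$cleavage_enrichment)
  q <- db$abundance / sum(db$abundance)
  sig <- db$features[db$features$category == "signal_peptide", , drop = FALSE]
  sig_end <- setNames(rep(NA_integer_, length(q)), names(db$sequences))
  sig_end[sig$accession] <- sig$end
  f <- cfg$full_length_fraction
  pf <- cfg$fragment_probs

  Tm <- matrix(0, 20L, 20L, dimnames = list(AA_STANDARD, AA_STANDARD))
  Bm <- Tm
  aid <- function(ch) match(ch, AA_STANDARD)
  add <- function(M, ai, bi, w) {
    agg <- rowsum(w, group = (bi - 1L) * 20L + ai)
    pos <- as.integer(rownames(agg))
    M[pos] <- M[pos] + agg[, 1L]
    M
  }

  for (a_ in names(db$sequences)) {
    bi <- .bond_info(db$sequences[[a_]], W, cfg)
    qa <- q[[a_]]
    ai <- aid(bi$a)
    bj <- aid(bi$b)
    p_sig <- if (is.na(sig_end[[a_]])) 0 else cfg$signal_fraction
    p_ins <- cfg$insource_fraction
    p_hyd <- 1 - p_sig - p_ins

    ## bond hydrolysis: joint (cut bond, emitted side) distribution
    uN <- bi$w_hyd * pf[["N"]] * bi$valid_n
    uC <- bi$w_hyd * pf[["C"]] * bi$valid_c
    uB <- bi$w_hyd * pf[["both"]] * (bi$valid_n & bi$valid_c)
    Z <- sum(uN) + sum(uC) + sum(uB)
    if (p_hyd > 0 && Z > 0) {
      pN <- uN / Z
      pC <- uC / Z
      pB <- uB / Z
      ## one site per emitted fragment, two for "both"; all at the cut pair
      Tm <- add(Tm, ai, bj, qa * p_hyd * (pN + pC + 2 * pB))
      ## bond k survives in the fragment(s): N-side keeps bonds < j,
      ## C-side keeps bonds > j, "both" keeps all but the cut bond
      nb <- bi$L - 1L
      SN <- rev(cumsum(rev(pN)))              # sum_{j >= k} pN(j)
      inc_n <- c(SN[-1L], 0)                  # sum_{j > k}
      CC <- cumsum(pC)                        # sum_{j <= k} pC(j)
      inc_c <- c(0, CC[-nb])                  # sum_{j < k}
      inc_b <- sum(pB) - pB
      Bm <- add(Bm, ai, bj, qa * (1 - f) * p_hyd * (inc_n + inc_c + inc_b))
    }
    ## in-source: C-side (y-ion) fragment only, proline-biased bond choice
    if (p_ins > 0 && sum(bi$w_ins) > 0) {
      pI <- bi$w_ins / sum(bi$w_ins)
      Tm <- add(Tm, ai, bj, qa * p_ins * pI)
      nb <- bi$L - 1L
      CI <- cumsum(pI)
      inc_i <- c(0, CI[-nb])
      Bm <- add(Bm, ai, bj, qa * (1 - f) * p_ins * inc_i)
    }
    ## signal-peptide cleavage: one N site at the signal end bond
    if (p_sig > 0) {
      e <- sig_end[[a_]]
      Tm[ai[e], bj[e]] <- Tm[ai[e], bj[e]] + qa * p_sig
      keep <- seq_along(ai) > e
      if (any(keep)) {
        Bm <- add(Bm, ai[keep], bj[keep], rep(qa * (1 - f) * p_sig, sum(keep)))
      }
    }
    ## full-length records: all bonds, minus the first with Met excision
    w_fl <- rep(qa * f, length(ai))
    if (bi$a[1L] == "M") w_fl[1L] <- w_fl[1L] * (1 - cfg$met_excision_prob)
    Bm <- add(Bm, ai, bj, w_fl)
  }
  t_share <- Tm / sum(Tm)
  b_share <- Bm / sum(Bm)
  nf <- log2(t_share / b_share)
  nf[Bm == 0 | Tm == 0] <- NA_real_
  structure(nf[pair[1L], pair[2L]], matrix = nf)
}
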