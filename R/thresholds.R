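#' Pipeline thresholds
#'
#' Returns the full set of numeric parameters driving the pipeline, with
#' defaults matching the published procedure: a 4 kb vicinity window around RE
#' genes, a 4 kb separation rule for split R-M systems, a 20 kb
#' mobile-element neighborhood, E-value cutoffs of 0.01 (vicinity ORF scan)
#' and 0.001 (methyl-directed RE screen), best-bidirectional-hit orthology at
#' >40\% identity over 80\% of the longer sequence for REs and >50\%/80\% for
#' MTases, the truncation rule (homologs at >20\% identity, query shorter by
#' 20\% or more), and single-linkage clustering at >40\% identity over 60\% of
#' each sequence.
#'
#' All identity/coverage thresholds are compared with strict inequality
#' (the published rules are written as ">").
#'
#' @param ... named overrides for any field.
#' @return A named list of class `rm_thresholds`.
#' @examples
#' th <- rm_thresholds()
#' th$vicinity_bp
#' rm_thresholds(bootstrap_reps = 500)$bootstrap_reps
#' @export
rm_thresholds <- function(...) {
  th <- list(
    vicinity_bp          = 4000L,
    separated_bp         = 4000L,
    neighborhood_bp      = 20000L,
    orf_evalue           = 0.01,
    typeiv_evalue        = 0.001,
    re_ortho_identity    = 0.40,
    re_ortho_coverage    = 0.80,
    mtase_ortho_identity = 0.50,
    mtase_ortho_coverage = 0.80,
    trunc_homolog_identity = 0.20,
    trunc_length_fraction  = 0.80,
    trunc_evalue           = 0.01,  # significance gate implicit in "homolog"
    cluster_identity     = 0.40,
    cluster_coverage     = 0.60,
    bootstrap_reps       = 200L,
    # operational parameters not fixed by the published rules
    min_orf_bp           = 150L,   # six-frame scan: minimum ORF length (50 aa)
    orf_ref_coverage     = 0.80,   # ORF counts as full-length MTase above this
    gap_opening          = 11,
    gap_extension        = 1,
    karlin_lambda        = 0.267,  # gapped BLOSUM62 11/1
    karlin_k             = 0.041
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(th))
    if (length(bad)) stop("unknown threshold field(s): ", paste(bad, collapse = ", "))
    th[names(dots)] <- dots
  }
  validate_thresholds(th)
  structure(th, class = "rm_thresholds")
}

validate_thresholds <- function(th) {
  fracs <- c("re_ortho_identity", "re_ortho_coverage", "mtase_ortho_identity",
             "mtase_ortho_coverage", "trunc_homolog_identity",
             "trunc_length_fraction", "cluster_identity", "cluster_coverage",
             "orf_ref_coverage")
  for (f in fracs) {
    v <- th[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop("threshold '", f, "' must be a fraction in (0, 1]")
  }
  bps <- c("vicinity_bp", "separated_bp", "neighborhood_bp", "min_orf_bp")
  for (f in bps) {
    v <- th[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("threshold '", f, "' must be a positive integer number of bp")
  }
  for (f in c("orf_evalue", "typeiv_evalue", "trunc_evalue")) {
    if (!is.numeric(th[[f]]) || th[[f]] <= 0)
      stop("threshold '", f, "' must be > 0")
  }
  if (th$bootstrap_reps < 1) stop("bootstrap_reps must be >= 1")
  invisible(th)
}
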