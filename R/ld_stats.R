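# Allele frequencies, ancestral-haplotype inference and the
# Bengtsson-Thomson linkage-disequilibrium index
#   delta = (p_D - p_N) / (1 - p_N)
# where p_D is the frequency of the ancestral allele set on disease
# (carrier) chromosomes and p_N the same frequency on normal (control)
# chromosomes. delta = 1 means complete association (no decay), 0 none.

#' Construct an ancestral haplotype
#'
#' Per marker, a non-empty set of founder repeat numbers. Usually each set
#' is a singleton; a two-allele set encodes cases where carriers share two
#' repeat numbers at one locus (e.g. a single early recombination or
#' mutation at the closest marker, as at D1S218 with repeats 24/25).
#'
#' @param sets named list (one element per map marker) of integer vectors.
#' @param map a [marker_map()].
#' @return Object of class `ancestral_haplotype`: the list reordered to map
#'   order.
#' @export
ancestral_haplotype <- function(sets, map) {
  stopifnot(inherits(map, "marker_map"))
  if (!setequal(names(sets), map$marker)) {
    stop("ancestral haplotype must name exactly the map markers")
  }
  sets <- lapply(sets[map$marker], function(x) {
    x <- sort(unique(as.integer(x)))
    if (length(x) == 0 || anyNA(x)) stop("ancestral allele sets must be non-empty integers")
    x
  })
  structure(sets, class = "ancestral_haplotype")
}

#' @export
print.ancestral_haplotype <- function(x, ...) {
  cat("Ancestral haplotype:\n")
  for (m in names(x)) cat("  ", m, ": ", paste(x[[m]], collapse = "/"), "\n", sep = "")
  invisible(x)
}

.select_records <- function(set, group, independent_only) {
  r <- set$records
  keep <- r$group == group
  if (independent_only) keep <- keep & r$independent
  r[keep, , drop = FALSE]
}

#' Allele frequency spectrum at one marker
#'
#' @param set a [haplotype_set()].
#' @param group `"carrier"` or `"control"`.
#' @param marker marker name.
#' @param independent_only use only chromosomes flagged independent
#'   (default `FALSE`: all chromosomes of the group).
#' @return data.frame with columns `allele`, `count`, `freq` (freq sums to
#'   1 over observed repeat numbers); attribute `n` = chromosomes used.
#' @export
allele_frequencies <- function(set, group = c("carrier", "control"), marker,
                               independent_only = FALSE) {
  group <- match.arg(group)
  stopifnot(inherits(set, "haplotype_set"))
  if (!marker %in% set$map$marker) stop("unknown marker: ", marker)
  r <- .select_records(set, group, independent_only)
  v <- r[[marker]]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    stop("no usable ", group, " chromosomes at marker ", marker,
         if (independent_only) " (independent only)" else "")
  }
  tab <- table(v)
  out <- data.frame(allele = as.integer(names(tab)),
                    count = as.integer(tab),
                    freq = as.numeric(tab) / length(v))
  attr(out, "n") <- length(v)
  out
}

#' Infer the ancestral haplotype from carrier chromosomes
#'
#' Takes, per marker, the modal repeat number among independent carrier
#' chromosomes. If the top two alleles tie exactly, or the runner-up count
#' reaches `near_tie` times the modal count, both enter the ancestral set
#' (this reproduces bi-allelic founder states at markers so close to the
#' mutation that a single early event split the founder lineage).
#'
#' @param set a [haplotype_set()].
#' @param near_tie runner-up inclusion threshold as a fraction of the modal
#'   count (default 0.8); ignored when `strict = TRUE`.
#' @param strict if `TRUE`, always return singletons, breaking exact ties
#'   toward the smaller repeat number (deterministic mode for tests).
#' @return An [ancestral_haplotype()].
#' @export
infer_ancestral <- function(set, near_tie = 0.8, strict = FALSE) {
  stopifnot(inherits(set, "haplotype_set"))
  carriers <- .select_records(set, "carrier", independent_only = TRUE)
  if (nrow(carriers) == 0) stop("no independent carrier chromosomes")
  sets <- lapply(set$map$marker, function(m) {
    v <- carriers[[m]]
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("all carrier alleles missing at marker ", m)
    tab <- sort(table(v), decreasing = TRUE)
    top <- as.integer(names(tab)[1])
    if (strict || length(tab) == 1) {
      if (!strict && length(tab) == 1) return(top)
      ties <- as.integer(names(tab)[tab == tab[1]])
      return(min(ties))
    }
    if (tab[2] >= near_tie * tab[1]) {
      as.integer(names(tab)[1:2])
    } else {
      top
    }
  })
  names(sets) <- set$map$marker
  ancestral_haplotype(sets, set$map)
}

#' Bengtsson-Thomson LD index per marker
#'
#' For each marker, computes the frequency of the ancestral allele set on
#' carrier chromosomes (`p_D`), on control chromosomes (`p_N`) and
#' `delta = (p_D - p_N) / (1 - p_N)`. Markers where every control
#' chromosome carries an ancestral allele (`p_N = 1`) have undefined delta
#' and are returned as `NA` with a warning; markers with `delta <= 0` are
#' flagged non-informative (they carry no founder signal and are excluded
#' from age estimation by default).
#'
#' @param set a [haplotype_set()].
#' @param anc an [ancestral_haplotype()].
#' @param independent_only use only independent carrier chromosomes
#'   (default `TRUE`, matching the analysis of unrelated carriers; controls
#'   always use all control chromosomes).
#' @return data.frame of class `delta_table` with columns `marker`, `p_D`,
#'   `p_N`, `delta`, `n_D`, `n_N`, `informative`.
#' @export
compute_delta <- function(set, anc, independent_only = TRUE) {
  stopifnot(inherits(set, "haplotype_set"), inherits(anc, "ancestral_haplotype"))
  carriers <- .select_records(set, "carrier", independent_only)
  controls <- .select_records(set, "control", independent_only = FALSE)
  rows <- lapply(set$map$marker, function(m) {
    cv <- carriers[[m]]; cv <- cv[!is.na(cv)]
    nv <- controls[[m]]; nv <- nv[!is.na(nv)]
    if (length(cv) == 0 || length(nv) == 0) {
      stop("need >=1 carrier and >=1 control chromosome with non-missing ",
           "alleles at marker ", m)
    }
    p_D <- mean(cv %in% anc[[m]])
    p_N <- mean(nv %in% anc[[m]])
    delta <- if (p_N < 1) (p_D - p_N) / (1 - p_N) else NA_real_
    data.frame(marker = m, p_D = p_D, p_N = p_N, delta = delta,
               n_D = length(cv), n_N = length(nv))
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$delta)) {
    warning("delta undefined (p_N = 1) at marker(s): ",
            paste(out$marker[is.na(out$delta)], collapse = ", "))
  }
  out$informative <- !is.na(out$delta) & out$delta > 0
  if (any(!out$informative & !is.na(out$delta))) {
    warning("non-informative marker(s) (delta <= 0): ",
            paste(out$marker[!out$informative & !is.na(out$delta)],
                  collapse = ", "))
  }
  structure(out, class = c("delta_table", "data.frame"))
}

#' Observed proportion of ancestral haplotypes at one marker
#'
#' The fraction of carrier chromosomes whose allele lies in the ancestral
#' set; this is the target the Markov transition-matrix iteration runs
#' down to.
#'
#' @inheritParams compute_delta
#' @param marker marker name.
#' @return list with `p_obs`, `count`, `n`.
#' @export
ancestral_proportion <- function(set, anc, marker, independent_only = TRUE) {
  stopifnot(inherits(set, "haplotype_set"), inherits(anc, "ancestral_haplotype"))
  if (!marker %in% set$map$marker) stop("unknown marker: ", marker)
  carriers <- .select_records(set, "carrier", independent_only)
  v <- carriers[[marker]]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no carrier chromosomes with non-missing allele at ", marker)
  list(p_obs = mean(v %in% anc[[marker]]),
       count = sum(v %in% anc[[marker]]),
       n = length(v))
}
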