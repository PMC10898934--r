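#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two GWAS summary tables on shared variant ids and resolves
#' effect-allele orientation so that every kept variant reports both
#' associations for the same allele. Four allele configurations are
#' recognized per variant: an exact match (kept as-is), a swap (outcome
#' beta sign and eaf flipped), a strand-complement match (complemented,
#' then kept), and a complement-swap (complemented and flipped). Variants
#' with incompatible allele pairs are removed. Palindromic variants (A/T
#' or C/G), whose strand cannot be resolved from the alleles alone, are
#' handled by `palindrome_policy`:
#' \describe{
#'   \item{`"remove"`}{drop them (the default, the conservative choice);}
#'   \item{`"infer"`}{align by allele frequency when both frequencies are
#'     far from 0.5 (|eaf - 0.5| > `eaf_margin` in both tables), dropping
#'     ambiguous ones;}
#'   \item{`"keep"`}{treat them like any other variant (only safe when
#'     both tables are known to be on the same strand).}
#' }
#'
#' @param exposure,outcome `summary_stats` tables keyed by variant id.
#' @param palindrome_policy `"remove"` (default), `"infer"` or `"keep"`.
#' @param eaf_margin Frequency margin for `"infer"` (default 0.08).
#' @return An object of class `harmonized_pair`: list with aligned
#'   `exposure` and `outcome` tables (identical allele designations) and
#'   an `action` data.frame logging, for every input variant, one of
#'   `kept`, `flipped`, `removed:palindromic`, `removed:incompatible`,
#'   `removed:missing`.
#' @examples
#' ss <- simulate_summary_stats(12, true_effect = 0.1, seed = 3)
#' h <- harmonize(ss$exposure, ss$outcome)
#' table(h$action$action)
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("remove", "infer", "keep"),
                      eaf_margin = 0.08) {
  exposure <- summary_stats(exposure)
  outcome <- summary_stats(outcome)
  palindrome_policy <- match.arg(palindrome_policy)

  all_ids <- union(exposure$id, outcome$id)
  action <- stats::setNames(rep("removed:missing", length(all_ids)), all_ids)
  shared <- intersect(exposure$id, outcome$id)
  if (length(shared) == 0) stop("no variants shared between the two tables")

  ex <- exposure[match(shared, exposure$id), ]
  ou <- outcome[match(shared, outcome$id), ]

  keep <- logical(length(shared))
  for (i in seq_along(shared)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal && palindrome_policy == "remove") {
      action[shared[i]] <- "removed:palindromic"
      next
    }
    if (pal && palindrome_policy == "infer" &&
        (abs(ex$eaf[i] - 0.5) <= eaf_margin ||
         abs(ou$eaf[i] - 0.5) <= eaf_margin)) {
      action[shared[i]] <- "removed:palindromic"
      next
    }

    if (pal && palindrome_policy == "infer") {
      # strand is unresolvable from the alleles; orient by frequency
      if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        action[shared[i]] <- "removed:incompatible"
        next
      }
      act <- if (sign(ex$eaf[i] - 0.5) != sign(ou$eaf[i] - 0.5))
        "flipped" else "kept"
    } else if (ea_y == ea_x && oa_y == oa_x) {
      act <- "kept"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      act <- "flipped"
    } else if (!pal && complement(ea_y) == ea_x && complement(oa_y) == oa_x) {
      ou$effect_allele[i] <- ea_x; ou$other_allele[i] <- oa_x
      act <- "kept"
    } else if (!pal && complement(ea_y) == oa_x && complement(oa_y) == ea_x) {
      ou$effect_allele[i] <- oa_x; ou$other_allele[i] <- ea_x
      act <- "flipped"
    } else {
      action[shared[i]] <- "removed:incompatible"
      next
    }
    if (act == "flipped") {
      ou$effect_allele[i] <- ea_x
      ou$other_allele[i] <- oa_x
      ou$beta[i] <- -ou$beta[i]
      ou$eaf[i] <- 1 - ou$eaf[i]
    }
    action[shared[i]] <- act
    keep[i] <- TRUE
  }

  res <- list(
    exposure = summary_stats(ex[keep, , drop = FALSE]),
    outcome = summary_stats(ou[keep, , drop = FALSE]),
    action = data.frame(id = all_ids, action = unname(action[all_ids]),
                        stringsAsFactors = FALSE))
  class(res) <- "harmonized_pair"
  res
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" && a2 == "T") || (a1 == "T" && a2 == "A") ||
    (a1 == "C" && a2 == "G") || (a1 == "G" && a2 == "C")
}

complement <- function(base) {
  c(A = "T", T = "A", C = "G", G = "C")[[base]]
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat("Harmonized summary-data pair:", nrow(x$exposure), "variants kept\n")
  print(table(x$action$action))
  invisible(x)
}

#' Greedy LD pruning of a summary-statistics table
#'
#' Orders variants by association strength (|beta|/se, descending) and
#' keeps each variant only if its squared correlation with every
#' already-kept variant is below `r2_threshold` — the standard clumping
#' convention.
#'
#' @param stats A `summary_stats` table.
#' @param ld Square correlation matrix (not squared), symmetric with unit
#'   diagonal, rows/columns aligned to `stats$id` (dimnames checked when
#'   present).
#' @param r2_threshold Squared-correlation threshold (default 0.24, below
#'   which uncorrelated instruments are conventionally assumed).
#' @return The pruned `summary_stats` table, with the dropped ids in
#'   attribute `pruned`.
#' @export
ld_prune <- function(stats, ld, r2_threshold = 0.24) {
  stats <- summary_stats(stats)
  ld <- as.matrix(ld)
  if (nrow(ld) != nrow(stats) || ncol(ld) != nrow(stats))
    stop("LD matrix dimensions do not match the summary table")
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)))
    stop("LD matrix must be symmetric")
  if (!is.null(rownames(ld)) && !identical(rownames(ld), stats$id))
    stop("LD matrix row names do not align with variant ids")

  ord <- order(-abs(stats$beta) / stats$se)
  kept <- integer(0)
  for (j in ord) {
    if (all(ld[j, kept]^2 < r2_threshold)) kept <- c(kept, j)
  }
  kept <- sort(kept)
  out <- summary_stats(stats[kept, , drop = FALSE])
  attr(out, "pruned") <- stats$id[setdiff(seq_len(nrow(stats)), kept)]
  out
}
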