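# Sector-wise paired delta-Tm localization analysis: the globe is divided
# into 16 anatomical sectors (sector 2 = injection site); each treated
# sector is compared with the corresponding sector of the paired control
# eye by a paired t-test.

#' Static 16-sector anatomical layout
#'
#' Sector labels for reporting: sector 2 is the injection site (12 o'clock,
#' just anterior to the equator), 1 and 3 flank it, 4-6 are superonasal,
#' 7-9 superotemporal, 10-11 medial, 12-13 lateral, 15 is at 6 o'clock with
#' 14 and 16 adjacent.
#'
#' @return Data frame with columns `sector`, `region`, `row`, `col` (a
#'   coarse grid position used by the text map rendering).
#' @export
sector_layout <- function() {
  data.frame(
    sector = 1:16,
    region = c("adjacent to injection site", "injection site (12 o'clock)",
               "adjacent to injection site",
               rep("superonasal", 3), rep("superotemporal", 3),
               rep("medial orbital wall", 2), rep("lateral orbital wall", 2),
               "adjacent inferior", "inferior (6 o'clock)",
               "adjacent inferior"),
    row = c(1, 1, 1, 2, 2, 2, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4),
    col = c(2, 3, 4, 1, 2, 3, 4, 5, 6, 1, 2, 5, 6, 2, 3, 4)
  )
}

validate_sector_table <- function(table) {
  need <- c("rabbit_id", "sector", "treated_tm", "control_tm")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("sector table needs columns ", paste(need, collapse = ", "))
  }
  if (any(!table$sector %in% 1:16)) stop("sector must be in 1..16")
  if (anyDuplicated(table[, c("rabbit_id", "sector")])) {
    stop("duplicate (rabbit, sector) rows")
  }
  if (!all(is.finite(table$treated_tm)) || !all(is.finite(table$control_tm))) {
    stop("Tm values must be finite")
  }
  missing <- setdiff(1:16, unique(table$sector))
  if (length(missing)) {
    warning("no measurements for sector(s) ",
            paste(missing, collapse = ", "))
  }
  invisible(table)
}

#' Per-sector paired delta-Tm summaries
#'
#' Computes, for each sector present in the table, the mean and sample SD of
#' the within-animal treated-minus-control Tm differences.
#'
#' @param table Sector table: data frame with `rabbit_id`, `sector`,
#'   `treated_tm`, `control_tm` (as from [generate_tm_table()]).
#' @return Data frame with `sector`, `n`, `delta_mean`, `delta_sd`.
#' @export
sector_delta <- function(table) {
  validate_sector_table(table)
  d <- table$treated_tm - table$control_tm
  out <- do.call(rbind, lapply(sort(unique(table$sector)), function(s) {
    ds <- d[table$sector == s]
    data.frame(sector = s, n = length(ds), delta_mean = mean(ds),
               delta_sd = if (length(ds) > 1) stats::sd(ds) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Per-sector paired t-tests
#'
#' Extends [sector_delta()] with a two-sided paired t-test per sector and a
#' significance flag at `alpha`. Sectors whose differences have zero
#' variance do not crash the analysis: they are flagged `degenerate` and get
#' the limiting p (0 for a nonzero mean difference, 1 otherwise). No
#' multiple-testing correction is applied by default, matching the reporting
#' of raw per-sector paired tests; set `p_adjust` to a [stats::p.adjust()]
#' method to change that.
#'
#' @inheritParams sector_delta
#' @param alpha Two-sided significance level (default 0.05).
#' @param p_adjust Multiple-testing correction method (default `"none"`).
#' @return Data frame with `sector`, `n`, `delta_mean`, `delta_sd`,
#'   `p_value`, `significant`, `degenerate`.
#' @export
sector_tests <- function(table, alpha = 0.05, p_adjust = "none") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  res <- sector_delta(table)
  d <- table$treated_tm - table$control_tm
  res$p_value <- NA_real_
  res$degenerate <- FALSE
  for (i in seq_len(nrow(res))) {
    ds <- d[table$sector == res$sector[i]]
    if (length(ds) < 2) {
      res$degenerate[i] <- TRUE
      next
    }
    if (stats::sd(ds) == 0) {
      res$degenerate[i] <- TRUE
      res$p_value[i] <- if (mean(ds) != 0) 0 else 1
    } else {
      res$p_value[i] <- stats::t.test(ds)$p.value
    }
  }
  res$p_value <- stats::p.adjust(res$p_value, method = p_adjust)
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res
}

#' Zone of effect: the significant sectors
#'
#' Extracts the ordered list of significant sectors from a [sector_tests()]
#' result and renders a plain-text 16-cell map mirroring the anatomical
#' layout (delta-Tm with SD and a significance mark per sector).
#'
#' @param results Data frame from [sector_tests()].
#' @return A list of class `zone_of_effect` with `sectors` (sorted
#'   significant sectors), `map` (results joined with [sector_layout()]) and
#'   `text` (the rendered layout, one string per line).
#' @export
zone_of_effect <- function(results) {
  if (!all(c("sector", "delta_mean", "significant") %in% names(results))) {
    stop("expected a sector_tests() result")
  }
  sig <- sort(results$sector[results$significant])
  lay <- merge(sector_layout(), results, by = "sector", all.x = TRUE)
  lines <- character(0)
  for (r in sort(unique(lay$row))) {
    cells <- lay[lay$row == r, ]
    cells <- cells[order(cells$col), ]
    lines <- c(lines, paste(vapply(seq_len(nrow(cells)), function(i) {
      if (is.na(cells$delta_mean[i])) {
        sprintf("[%2d:    --    ]", cells$sector[i])
      } else {
        sprintf("[%2d:%5.1f%s%s]", cells$sector[i], cells$delta_mean[i],
                if (!is.na(cells$delta_sd[i])) {
                  sprintf("±%.1f", cells$delta_sd[i])
                } else "     ",
                if (isTRUE(cells$significant[i])) "*" else " ")
      }
    }, character(1)), collapse = " "))
  }
  structure(list(sectors = sig, map = lay, text = lines),
            class = "zone_of_effect")
}

#' @exportS3Method base::print
print.zone_of_effect <- function(x, ...) {
  cat("zone of effect (significant sectors): ",
      if (length(x$sectors)) paste(x$sectors, collapse = ", ") else "none",
      "\n", sep = "")
  cat(x$text, sep = "\n")
  invisible(x)
}
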