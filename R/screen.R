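#' Screening hit rate
#'
#' Percentage of hits among tested items: 100 * n_hits / n_total. The raw
#' unrounded value is kept alongside a 2-decimal display form (half-up
#' rounding), the convention used when reporting virtual- and in-vitro-
#' screen hit rates.
#'
#' @param n_hits Number of hits, 0 <= n_hits <= n_total.
#' @param n_total Number tested, positive.
#' @return Object of class `hit_rate`: list with `value` (unrounded
#'   percent) and `display` (e.g. `"1.22%"`).
#' @examples
#' hit_rate(133, 2276 + 8607) # 1.22%
#' hit_rate(1, 133)           # 0.75%
#' @export
hit_rate <- function(n_hits, n_total) {
  if (length(n_total) != 1 || n_total <= 0) stop("hit_rate: n_total must be positive")
  if (n_hits < 0 || n_hits > n_total)
    stop("hit_rate: n_hits must lie in [0, n_total]")
  value <- 100 * n_hits / n_total
  structure(list(value = value,
                 display = paste0(format_half_up(value, 2), "%")),
            class = "hit_rate")
}

#' @export
print.hit_rate <- function(x, ...) {
  cat(sprintf("%s (raw %.6g%%)\n", x$display, x$value))
  invisible(x)
}

# half-up decimal rounding (base round() is round-half-even)
format_half_up <- function(x, digits) {
  scaled <- floor(x * 10^digits + 0.5) / 10^digits
  formatC(scaled, format = "f", digits = digits)
}

#' Kyte-Doolittle hydropathy scale
#'
#' The published per-residue hydropathy values, from -4.5 (Arg) to +4.5
#' (Ile), keyed by 1-letter amino-acid code. Embedded as the single source
#' of truth for hydropathy profiling.
#'
#' @return Named numeric vector of length 20.
#' @export
kyte_doolittle_scale <- function() {
  c(I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
    E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

#' Per-residue hydropathy profile
#'
#' Looks up the Kyte-Doolittle hydropathy of each residue of a protein
#' sequence and smooths it with a centered sliding-window mean. Positions
#' closer to either end than the half-window have no smoothed value.
#'
#' @param sequence 1-letter amino-acid string (standard 20 residues; case
#'   insensitive).
#' @param window Odd positive window width (default 9, the scale authors'
#'   recommendation for surface regions; 1 disables smoothing).
#' @return Object of class `hydropathy_profile`: data.frame with columns
#'   `position`, `residue`, `value`, `smoothed`.
#' @examples
#' hydropathy_profile("GEALI", window = 1)
#' @export
hydropathy_profile <- function(sequence, window = 9) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  if (window < 1 || window %% 2 != 1) stop("hydropathy_profile: window must be odd and >= 1")
  aa <- strsplit(toupper(sequence), "")[[1]]
  scale <- kyte_doolittle_scale()
  bad <- which(!aa %in% names(scale))
  if (length(bad))
    stop(sprintf("hydropathy_profile: unknown residue '%s' at position %d",
                 aa[bad[1]], bad[1]))
  values <- unname(scale[aa])
  smoothed <- if (window == 1) values else {
    s <- as.numeric(stats::filter(values, rep(1 / window, window), sides = 2))
    s
  }
  structure(data.frame(position = seq_along(aa), residue = aa,
                       value = values, smoothed = smoothed,
                       stringsAsFactors = FALSE),
            class = c("hydropathy_profile", "data.frame"),
            window = window)
}

#' Summarize a compound screen
#'
#' Per-library and pooled bookkeeping for a two-stage screen: compounds are
#' docked virtually, a subset is selected for purchase, and a subset of
#' those shows activity in vitro. The virtual hit rate is
#' selected / docked and the in-vitro hit rate is active / selected,
#' both in percent.
#'
#' @param records data.frame with columns `library` (character), `selected`
#'   (logical), `active` (logical); one row per docked compound.
#' @return data.frame with one row per library plus a `"pooled"` row:
#'   `library`, `n_docked`, `n_selected`, `n_active`, `virtual_hit_rate`,
#'   `invitro_hit_rate` (percent; `NA` when the denominator is 0).
#' @export
summarize_screen <- function(records) {
  need <- c("library", "selected", "active")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("summarize_screen: missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0)
    return(data.frame(library = character(0), n_docked = integer(0),
                      n_selected = integer(0), n_active = integer(0),
                      virtual_hit_rate = numeric(0),
                      invitro_hit_rate = numeric(0), stringsAsFactors = FALSE))
  records$selected <- as.logical(records$selected)
  records$active <- as.logical(records$active)
  if (any(records$active & !records$selected))
    stop("summarize_screen: a compound cannot be active without being selected")
  one <- function(name, sub) {
    nd <- nrow(sub); ns <- sum(sub$selected); na_ <- sum(sub$active)
    data.frame(library = name, n_docked = nd, n_selected = ns, n_active = na_,
               virtual_hit_rate = if (nd > 0) 100 * ns / nd else NA_real_,
               invitro_hit_rate = if (ns > 0) 100 * na_ / ns else NA_real_,
               stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(split(records, records$library),
                               function(s) one(s$library[1], s)))
  rownames(per) <- NULL
  rbind(per, one("pooled", records))
}
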