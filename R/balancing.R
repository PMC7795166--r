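#' Per-file retention cap for under-sampling
#'
#' When behaviour b occurs in `k_b` of the data files and the balancing
#' budget is `s_min` samples per behaviour, each file may contribute at
#' most `floor(s_min / k_b)` samples of b. Flooring guarantees the
#' per-behaviour total never exceeds `s_min`.
#'
#' @param s_min Target total sample count per behaviour (> 0).
#' @param k_b Number of files containing at least one sample of the
#'   behaviour (>= 1).
#' @return Integer cap (>= 1).
#' @export
per_file_cap <- function(s_min, k_b) {
  if (k_b < 1) {
    stop("behaviour absent from every file (k_b = 0)", call. = FALSE)
  }
  if (s_min <= 0) stop("s_min must be positive", call. = FALSE)
  cap <- as.integer(s_min %/% k_b)
  if (cap < 1L) {
    stop("cap floor(s_min / k_b) = 0: s_min = ", s_min, " cannot be ",
         "spread over ", k_b, " files; raise s_min", call. = FALSE)
  }
  cap
}

#' Under-sample labelled windows to balance behaviour classes
#'
#' For every (file, behaviour) group holding more than
#' `floor(s_min / k_b)` samples, a uniform random subset of exactly that
#' cap is kept; smaller groups are kept whole. `k_b` is the number of
#' files in which behaviour b occurs, so each behaviour's post-balance
#' total is at most `s_min`. Selection uses an RNG stream derived from
#' `seed` and the (file, behaviour) pair, so the result does not depend
#' on group iteration order and is reproducible.
#'
#' @param features A data.frame with columns `animal_id` and `label`
#'   (e.g. from [extract_features()]); rows with `NA` labels are
#'   dropped.
#' @param s_min Per-behaviour sample budget. The default `"auto"` uses
#'   the total count of the rarest behaviour across files.
#' @param seed Integer seed.
#' @return The balanced data.frame (a sub-multiset of the input rows),
#'   with a `retention` attribute: a per-(file, behaviour) data.frame of
#'   available vs. kept counts.
#' @export
balance_classes <- function(features, s_min = "auto", seed = 1L) {
  d <- features[!is.na(features$label), , drop = FALSE]
  if (nrow(d) == 0L) {
    stop("no labelled samples to balance", call. = FALSE)
  }
  class_tot <- table(d$label)
  if (identical(s_min, "auto")) {
    s_min <- as.integer(min(class_tot))
  }
  behaviours <- names(class_tot)
  files <- sort(unique(as.character(d$animal_id)))
  keep <- logical(nrow(d))
  rows <- list()
  for (b in behaviours) {
    in_b <- d$label == b
    files_b <- unique(as.character(d$animal_id[in_b]))
    cap <- per_file_cap(s_min, length(files_b))
    for (f in files_b) {
      g <- which(in_b & as.character(d$animal_id) == f)
      kept <- if (length(g) > cap) {
        old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
        set.seed(.group_seed(seed, f, b))
        sort(sample(g, cap))
      } else g
      keep[kept] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = f, behaviour = b, cap = cap,
        available = length(g), kept = length(kept),
        stringsAsFactors = FALSE)
    }
  }
  out <- d[keep, , drop = FALSE]
  attr(out, "retention") <- do.call(rbind, rows)
  attr(out, "s_min") <- s_min
  out
}

# Deterministic per-(file, behaviour) seed independent of iteration
# order, within 32-bit range.
.group_seed <- function(seed, file_id, behaviour) {
  h <- sum(utf8ToInt(paste0(file_id, "\r", behaviour)) *
             (seq_along(utf8ToInt(paste0(file_id, "\r", behaviour))) %% 31 + 1))
  (as.integer(seed) * 131071L + as.integer(h %% 16381L)) %% 2147483629L
}
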