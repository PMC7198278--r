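#' Entry-level genetic BLUPs from sparse trial records
#'
#' Fits the record-level mixed model
#' `y = mu + location + location:year + g + e` for one trait, with
#' `g ~ N(0, Va * K)` over entries mapped to records through an incidence
#' matrix and `e ~ N(0, Ve * I)`. Variance components come from [reml_fit()]
#' (one-dimensional REML over `Va/Ve`); the empirical BLUPs are the
#' conditional means of `g` at those estimates, reported as zero-centered
#' deviations. Duplicate (entry, location, year) records are averaged
#' first; location-by-year fixed-effect columns that are aliased (for
#' example a location observed in a single year) are dropped by QR rank
#' detection and reported in the result. Entries never phenotyped for the
#' trait receive no BLUP.
#'
#' @param table Long-format phenotype tibble with columns `entry`,
#'   `location`, `year`, `trait`, `value`.
#' @param trait Name of the trait to fit.
#' @param K A `kinship_matrix` covering every phenotyped entry.
#' @return A `blup_result`: `blups` (tibble: `entry`, `blup`, `n_obs`),
#'   `fit` (the [reml_fit()]), `h2`, `n_records_used`, `dropped_columns`.
#' @export
fit_blup <- function(table, trait, K) {
  tr <- trait
  recs <- table %>%
    filter(trait == tr, !is.na(value)) %>%
    group_by(entry, location, year) %>%
    summarise(value = mean(value), .groups = "drop")
  if (nrow(recs) == 0) {
    stop_sparsemet(sprintf("No records for trait '%s'.", tr),
                   "sparsemet_parameter_error")
  }
  if (length(unique(recs$location)) < 2) {
    stop_sparsemet("At least two locations are required.",
                   "sparsemet_parameter_error")
  }
  Km <- kinship_values(K)
  ids <- if (inherits(K, "kinship_matrix")) K$entry_ids else rownames(Km)
  entries <- sort(unique(recs$entry))
  missing <- setdiff(entries, ids)
  if (length(missing) > 0) {
    stop_sparsemet(
      sprintf("Entries missing from the kinship matrix: %s",
              paste(head(missing, 5), collapse = ", ")),
      "sparsemet_id_error"
    )
  }
  ksub <- match(entries, ids)
  Km <- Km[ksub, ksub, drop = FALSE]

  n <- nrow(recs)
  loc <- factor(recs$location)
  ly <- factor(paste(recs$location, recs$year, sep = ":"))
  X <- model.matrix(~ loc + ly)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep_cols)]
    X <- X[, keep_cols, drop = FALSE]
  }

  Z <- matrix(0, n, length(entries))
  Z[cbind(seq_len(n), match(recs$entry, entries))] <- 1

  # degenerate input: no variation at all
  if (sd(recs$value) == 0) {
    blups <- tibble(entry = entries, blup = 0,
                    n_obs = as.integer(colSums(Z)))
    return(structure(list(blups = blups, fit = NULL, h2 = 0,
                          n_records_used = n, dropped_columns = dropped),
                     class = "blup_result"))
  }

  fit <- reml_fit(recs$value, X, Km, Z = Z)

  # g_hat = lambda * K Z' V*^-1 r  with  V* = I + lambda Z K Z'
  b <- fit$beta
  r <- recs$value - as.numeric(X %*% b)
  Zr <- as.numeric(crossprod(Z, r))
  lambda <- fit$lambda
  if (lambda == 0) {
    g <- rep(0, length(entries))
  } else {
    C <- crossprod(Z)
    M <- diag(length(entries)) + lambda * Km %*% C
    ZVr <- Zr - lambda * as.numeric(C %*% solve(M, Km %*% Zr))
    g <- lambda * as.numeric(Km %*% ZVr)
  }
  g <- g - mean(g)  # reported as deviations

  blups <- tibble(entry = entries, blup = g,
                  n_obs = as.integer(colSums(Z)))
  structure(
    list(blups = blups, fit = fit,
         h2 = narrow_sense_h2(fit$Va, fit$Ve),
         n_records_used = n, dropped_columns = dropped),
    class = "blup_result"
  )
}

#' @export
print.blup_result <- function(x, ...) {
  cat("<blup_result> ", nrow(x$blups), " entries, ", x$n_records_used,
      " records, h2 = ", sprintf("%.3f", x$h2), "\n", sep = "")
  invisible(x)
}

#' Tidiers for sparsemet fits
#'
#' [generics::tidy()] and [generics::glance()] methods returning tibbles.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidiers
#' @rdname tidiers
#' @method tidy blup_result
#' @export
tidy.blup_result <- function(x, ...) x$blups

#' @rdname tidiers
#' @method glance blup_result
#' @export
glance.blup_result <- function(x, ...) {
  tibble(h2 = x$h2,
         Va = if (is.null(x$fit)) 0 else x$fit$Va,
         Ve = if (is.null(x$fit)) 0 else x$fit$Ve,
         n_entries = nrow(x$blups),
         n_records_used = x$n_records_used,
         n_dropped_columns = length(x$dropped_columns))
}

#' BLUPs for every trait in a phenotype table
#'
#' @param table Long-format phenotype tibble.
#' @param K A `kinship_matrix`.
#' @param traits Traits to fit (default: all present).
#' @return A named list of `blup_result` objects.
#' @export
fit_all_blups <- function(table, K, traits = NULL) {
  traits <- traits %||% sort(unique(table$trait))
  setNames(lapply(traits, function(tr) fit_blup(table, tr, K)), traits)
}

#' Assemble an entry x trait BLUP matrix
#'
#' @param blup_list Named list of `blup_result` objects (see
#'   [fit_all_blups()]).
#' @return A matrix with one row per entry (union over traits; `NA` where
#'   an entry lacks a BLUP) and one column per trait.
#' @export
blup_matrix <- function(blup_list) {
  entries <- sort(unique(unlist(lapply(blup_list, function(b) b$blups$entry))))
  out <- matrix(NA_real_, length(entries), length(blup_list),
                dimnames = list(entries, names(blup_list)))
  for (nm in names(blup_list)) {
    b <- blup_list[[nm]]$blups
    out[b$entry, nm] <- b$blup
  }
  out
}
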