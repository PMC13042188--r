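#' Read or write a feature table / z-matrix as TSV
#'
#' Text round-trips keep 12 significant digits.
#'
#' @param x A feature table or z-matrix tibble.
#' @param path File path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_feature_table <- function(x, path) {
  out <- dplyr::mutate(tibble::as_tibble(x), dplyr::across(
    dplyr::where(is.numeric), ~ signif(.x, 12)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_feature_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname table_io
#' @export
write_z_matrix <- function(x, path) {
  write_feature_table(x, path)
}

#' @rdname table_io
#' @param features Modelled feature columns (default: inferred from the
#'   header's `<band>_<roi>` names).
#' @export
read_z_matrix <- function(path, features = NULL) {
  as_z_matrix(readr::read_tsv(path, show_col_types = FALSE),
              features = features)
}

#' Serialize harmonization parameters to versioned JSON
#'
#' @param params A [fit_harmonization()] object.
#' @param path Output path.
#' @export
write_harmonization <- function(params, path) {
  doc <- list(
    format = "eegsustain-harmonization", version = 1L,
    n_hc = attr(params, "n_hc"),
    features = as.list(tibble::as_tibble(params))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_harmonization
#' @export
read_harmonization <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "eegsustain-harmonization")) {
    abort("Not a harmonization parameter file.")
  }
  params <- tibble::as_tibble(doc$features)
  attr(params, "n_hc") <- doc$n_hc
  attr(params, "modelled_features") <- params$feature
  class(params) <- c("harmonization_params", class(params))
  params
}

#' Serialize a fitted progression model to versioned JSON
#'
#' Sequences are stored as event-id lists along with fractions, the event
#' configuration, noise SDs and fit metadata; MCMC samples are stored
#' thinned as fitted.
#'
#' @param model A [sustain_fit()] object.
#' @param path Output path.
#' @export
write_progression_model <- function(model, path) {
  doc <- list(
    format = "eegsustain-model", version = 1L,
    biomarkers = model$cfg$biomarkers,
    z1 = model$cfg$z1, z2 = model$cfg$z2, z_max = model$cfg$z_max,
    sequences = model$sequences, fractions = model$fractions,
    sigma = model$sigma, loglik = model$loglik,
    n_subjects = model$n_subjects, C = model$C,
    seed = model$seed,
    samples = lapply(model$samples, function(m) {
      if (is.null(m) || nrow(m) == 0) list() else apply(m, 1, identity,
                                                        simplify = FALSE)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_progression_model
#' @export
read_progression_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "eegsustain-model")) {
    abort("Not a progression-model file.")
  }
  cfg <- event_config(doc$biomarkers, z1 = doc$z1, z2 = doc$z2,
                      z_max = doc$z_max)
  seqs <- if (is.matrix(doc$sequences)) {
    lapply(seq_len(nrow(doc$sequences)), function(i) doc$sequences[i, ])
  } else if (is.list(doc$sequences)) {
    lapply(doc$sequences, as.integer)
  } else {
    list(as.integer(doc$sequences))
  }
  samples <- lapply(doc$samples, function(s) {
    if (length(s) == 0) {
      matrix(integer(0), ncol = cfg$n_events)
    } else if (is.matrix(s)) {
      matrix(as.integer(s), ncol = cfg$n_events)
    } else {
      do.call(rbind, lapply(s, as.integer))
    }
  })
  structure(
    list(sequences = seqs, fractions = doc$fractions, cfg = cfg,
         sigma = doc$sigma, loglik = doc$loglik, samples = samples,
         n_subjects = doc$n_subjects, C = doc$C, control = NULL,
         seed = doc$seed, flat = FALSE, converged = TRUE),
    class = "progression_model"
  )
}
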