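#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname telex_tidiers
tidy.telex_de <- function(x, ...) {
  as_tibble(x)
}

#' Tidiers for telex result objects
#'
#' broom-style one-row (`glance()`) and per-term (`tidy()`) summaries.
#'
#' @param x A telex result object.
#' @param ... Unused.
#' @return A tibble.
#' @name telex_tidiers
NULL

#' @export
#' @rdname telex_tidiers
glance.telex_de <- function(x, ...) {
  n_de <- attr(x, "n_de") %||% c(up = sum(x$direction == "up"),
                                 down = sum(x$direction == "down"))
  tibble(
    contrast = attr(x, "contrast") %||% NA_character_,
    paired = attr(x, "paired") %||% NA,
    n_tested = nrow(x),
    n_up = unname(n_de["up"]), n_down = unname(n_de["down"]),
    common_dispersion = attr(x, "dispersion")$common %||% NA_real_
  )
}

#' @export
#' @rdname telex_tidiers
tidy.telex_boruta <- function(x, ...) as_tibble(x)

#' @export
#' @rdname telex_tidiers
glance.telex_boruta <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_confirmed = sum(x$status == "confirmed"),
    n_rejected = sum(x$status == "rejected"),
    n_tentative = sum(x$status == "tentative"),
    n_iterations = x$n_iterations[1]
  )
}

#' @export
#' @rdname telex_tidiers
tidy.telex_model <- function(x, ...) x$roc

#' @export
#' @rdname telex_tidiers
glance.telex_model <- function(x, ...) {
  tibble(
    auc = x$auc, accuracy = x$accuracy, cv_accuracy = x$cv_accuracy,
    n_features = length(x$features),
    n_train = length(x$split$train), n_test = length(x$split$test),
    positive = x$positive
  )
}

#' @export
#' @rdname telex_tidiers
tidy.telex_norm <- function(x, ...) as_tibble(x)

#' @export
#' @rdname telex_tidiers
glance.telex_pca <- function(x, ...) {
  ve <- attr(x, "variance_explained")
  tibble(separation = attr(x, "separation"),
         pc1_variance = ve[1], pc2_variance = ve[2] %||% NA_real_)
}
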