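#' Default gesture vocabulary
#'
#' The four gesture classes used throughout the toolkit, in canonical order:
#' needle entering, needle gripping (with the tweezers), needle passing, and
#' a catch-all "other" class for non-suturing activity (cleaning, pausing).
#'
#' @return Character vector of class names.
#' @export
gesture_vocabulary <- function() {
  c("entering", "gripping", "passing", "other")
}

match_class <- function(name, vocabulary) {
  id <- match(name, vocabulary)
  if (anyNA(id)) {
    stop("unknown class: ", paste(unique(name[is.na(id)]), collapse = ", "),
         call. = FALSE)
  }
  id
}
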