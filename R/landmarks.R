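#' Facial landmark schema
#'
#' Seven facial landmarks are tracked on a head-fixed mouse: both ears, the
#' upper and lower eyelid of each eye, and the nose. Their names and order
#' are fixed; every trajectory table must carry exactly these landmarks.
#'
#' @return Character vector of the 7 landmark names, in canonical order.
#' @export
#' @examples
#' landmark_names()
landmark_names <- function() {
  c("ear_left", "ear_right",
    "eyelid_upper_left", "eyelid_lower_left",
    "eyelid_upper_right", "eyelid_lower_right",
    "nose")
}

#' Composite scoring features
#'
#' The five features that are scored and weighted: each ear, each eye (an
#' eye owns its upper + lower eyelid pair), and the nose.
#'
#' @return Character vector of the 5 feature identifiers.
#' @export
feature_names <- function() {
  c("EAR_LEFT", "EAR_RIGHT", "EYE_LEFT", "EYE_RIGHT", "NOSE")
}

#' Landmarks backing a scoring feature
#'
#' @param feature One of [feature_names()].
#' @return Character vector of landmark names owned by the feature.
#' @export
feature_landmarks <- function(feature) {
  feature <- match.arg(feature, feature_names())
  switch(feature,
    EAR_LEFT  = "ear_left",
    EAR_RIGHT = "ear_right",
    EYE_LEFT  = c("eyelid_upper_left", "eyelid_lower_left"),
    EYE_RIGHT = c("eyelid_upper_right", "eyelid_lower_right"),
    NOSE      = "nose")
}

# column names of a landmark block in the wide per-frame table
landmark_cols <- function(landmark) {
  paste(landmark, c("x", "y", "likelihood"), sep = ".")
}

all_landmark_cols <- function() {
  unlist(lapply(landmark_names(), landmark_cols), use.names = FALSE)
}
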