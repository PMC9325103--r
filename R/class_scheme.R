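#' Extraocular-muscle class scheme
#'
#' The fixed label taxonomy shared by every component of the pipeline:
#' integer label 0 is background and labels 1..8 are the eight extraocular
#' muscle classes, left side first, in the order medial rectus, lateral
#' rectus, superior group, inferior rectus. The superior rectus and the
#' levator palpebrae superioris cannot be reliably separated on CT and are
#' always a single "superior group" class.
#'
#' Each muscle class carries a `side` (`"L"` or `"R"`) and a measurement
#' `axis` tag: thickness of the medial and lateral recti is a horizontal
#' diameter, thickness of the superior group and inferior rectus a vertical
#' diameter, on the coronal plane.
#'
#' @return A data.frame with columns `index` (0..8), `name`, `side`
#'   (`NA` for background) and `axis` (`"horizontal"`, `"vertical"` or `NA`).
#' @examples
#' class_scheme()
#' @export
class_scheme <- function() {
  data.frame(
    index = 0:8,
    name = c("background",
             "L-medial rectus", "L-lateral rectus",
             "L-superior group", "L-inferior rectus",
             "R-medial rectus", "R-lateral rectus",
             "R-superior group", "R-inferior rectus"),
    side = c(NA, rep("L", 4), rep("R", 4)),
    axis = c(NA, rep(c("horizontal", "horizontal", "vertical", "vertical"), 2)),
    stringsAsFactors = FALSE
  )
}

#' Muscle class indices
#'
#' @return Integer vector of the 8 non-background class indices in canonical
#'   order (left side first; medial, lateral, superior, inferior within a side).
#' @examples
#' muscle_classes()
#' @export
muscle_classes <- function() 1:8

#' Number of classes including background
#' @return 9
#' @export
n_classes <- function() 9L

#' Class name from index
#' @param index integer label(s) in 0..8
#' @return character vector of class names
#' @export
class_name <- function(index) {
  stopifnot(all(index %in% 0:8))
  class_scheme()$name[index + 1L]
}

#' Class index from name
#' @param name character class name(s) as listed by [class_scheme()]
#' @return integer label(s)
#' @export
class_index <- function(name) {
  sc <- class_scheme()
  i <- match(name, sc$name)
  if (anyNA(i)) stop("unknown class name: ", paste(name[is.na(i)], collapse = ", "))
  sc$index[i]
}

#' Export the class table as JSON
#'
#' Written alongside label volumes and reports so that downstream consumers
#' never have to hard-code the label taxonomy.
#'
#' @param path file to write; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
class_scheme_json <- function(path = NULL) {
  js <- jsonlite::toJSON(class_scheme(), dataframe = "rows", pretty = TRUE, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
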