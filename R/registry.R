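#' Evidence element registries
#'
#' The extraction targets are ten PICOS evidence elements, each typed with an
#' output granularity level: A (long sentence), B (short sentence), C
#' (phrase), D (number). The default registry carries the ten canonical
#' elements; the `"extended"` preset splits the five group-specific elements
#' into treatment/control sub-variants, giving 15 entity labels and hence a
#' 31-tag BIO inventory.
#'
#' @param preset `"default"` (10 elements, 21 BIO tags) or `"extended"`
#'   (15 elements, 31 BIO tags).
#' @return An object of class `element_registry`: a data.frame with columns
#'   `id`, `picos_category`, `level`, plus a `preset` attribute.
#' @examples
#' reg <- element_registry()
#' table(reg$level)
#' @export
element_registry <- function(preset = c("default", "extended")) {
  preset <- match.arg(preset)
  base <- data.frame(
    id = c("pop_number", "pop_age", "pop_source", "pop_diagnosis",
           "therapy", "out_adverse", "out_shedding",
           "des_missing", "des_blind", "des_random"),
    picos_category = c("Population", "Population", "Population", "Population",
                       "Intervention/Comparison", "Outcome", "Outcome",
                       "StudyDesign", "StudyDesign", "StudyDesign"),
    level = c("D", "C", "B", "A", "B", "C", "D", "D", "B", "B"),
    stringsAsFactors = FALSE
  )
  if (preset == "extended") {
    split_ids <- c("pop_number", "pop_age", "therapy", "out_adverse", "out_shedding")
    rows <- lapply(seq_len(nrow(base)), function(i) {
      row <- base[i, , drop = FALSE]
      if (row$id %in% split_ids) {
        t_row <- row; t_row$id <- paste0(row$id, "_t")
        c_row <- row; c_row$id <- paste0(row$id, "_c")
        rbind(t_row, c_row)
      } else row
    })
    base <- do.call(rbind, rows)
    rownames(base) <- NULL
  }
  new_element_registry(base, preset)
}

new_element_registry <- function(df, preset) {
  stopifnot(is.data.frame(df),
            all(c("id", "picos_category", "level") %in% names(df)))
  if (anyDuplicated(df$id)) {
    stop("duplicate element id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$level), c("A", "B", "C", "D"))
  if (length(bad)) stop("invalid level(s): ", paste(bad, collapse = ", "))
  structure(df, class = c("element_registry", "data.frame"), preset = preset)
}

#' Read an element registry from a YAML configuration
#'
#' The file lists elements in order, each with `picos_category` and `level`:
#' ```yaml
#' elements:
#'   - id: pop_number
#'     picos_category: Population
#'     level: D
#' ```
#'
#' @param path YAML file path.
#' @return An `element_registry`.
#' @export
read_registry_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$elements)) stop("registry YAML must have an 'elements' list")
  df <- do.call(rbind, lapply(cfg$elements, function(e) {
    for (f in c("id", "picos_category", "level")) {
      if (is.null(e[[f]])) stop("registry element missing field '", f, "'")
    }
    data.frame(id = e$id, picos_category = e$picos_category, level = e$level,
               stringsAsFactors = FALSE)
  }))
  new_element_registry(df, preset = if (is.null(cfg$preset)) "custom" else cfg$preset)
}

#' @export
print.element_registry <- function(x, ...) {
  cat("Element registry (preset '", attr(x, "preset"), "'): ",
      nrow(x), " elements, ", 2L * nrow(x) + 1L, " BIO tags\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

element_level <- function(registry, element) {
  i <- match(element, registry$id)
  if (anyNA(i)) stop("unknown element id(s): ",
                     paste(element[is.na(i)], collapse = ", "))
  registry$level[i]
}

#' BIO tag schema for a registry
#'
#' Tags are `O` plus `B-<id>` / `I-<id>` per element, in registry order, so
#' the inventory size is `2 * n_elements + 1` (21 for the default preset,
#' 31 for the extended one).
#'
#' @param registry An `element_registry`.
#' @return An object of class `tag_schema` with components `tags` (ordered
#'   character vector, `O` first), `element_of` (named map tag -> element id,
#'   `NA` for `O`), and `registry`.
#' @export
tag_schema <- function(registry) {
  stopifnot(inherits(registry, "element_registry"))
  tags <- c("O", as.vector(rbind(paste0("B-", registry$id),
                                 paste0("I-", registry$id))))
  element_of <- c(NA_character_, as.vector(rbind(registry$id, registry$id)))
  names(element_of) <- tags
  structure(list(tags = tags, element_of = element_of, registry = registry),
            class = "tag_schema")
}

#' @export
print.tag_schema <- function(x, ...) {
  cat("BIO tag schema: ", length(x$tags), " tags over ",
      nrow(x$registry), " elements\n", sep = "")
  invisible(x)
}

tag_index <- function(schema, tags) {
  i <- match(tags, schema$tags)
  if (anyNA(i)) stop("unknown tag(s): ",
                     paste(unique(tags[is.na(i)]), collapse = ", "))
  i
}
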