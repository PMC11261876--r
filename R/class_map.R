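#' Construct a ClassMap
#'
#' A ClassMap carries the cancer-type -> origin-class recoding, the set of
#' cancer types treated as squamous-cell histology (which get their own DMC
#' panel and image half), and the types excluded from the cohort outright.
#'
#' @param type_to_class Named character vector mapping cancer-type codes to
#'   origin-class labels.
#' @param squamous_types Character vector of cancer-type codes forming the
#'   squamous group; must be a subset of `names(type_to_class)`.
#' @param excluded_types Character vector of cancer-type codes dropped from
#'   the cohort; disjoint from `names(type_to_class)`.
#' @return An object of class `ClassMap`.
#' @export
ClassMap <- function(type_to_class, squamous_types = character(),
                     excluded_types = character()) {
  if (is.null(names(type_to_class)) || anyDuplicated(names(type_to_class)))
    stopf("'type_to_class' must be a uniquely named character vector")
  if (!all(squamous_types %in% names(type_to_class)))
    stopf("squamous_types not in the map: %s",
          paste(setdiff(squamous_types, names(type_to_class)), collapse = ", "))
  if (length(intersect(excluded_types, names(type_to_class))))
    stopf("excluded_types must not appear in type_to_class")
  structure(list(type_to_class = type_to_class,
                 squamous_types = sort(squamous_types),
                 excluded_types = sort(excluded_types)),
            class = "ClassMap")
}

#' Default TCGA class map: 29 cancer types, 18 origin classes
#'
#' Recodes the 29 retained TCGA solid-tumour types into 18 origin classes by
#' primary organ or histology: organ groups (colorectal, oesophagogastric,
#' kidney, hepatobiliary, brain, soft tissue, gynecologic), nine singleton
#' organ classes, and the five squamous-histology types (head & neck,
#' lung squamous, esophageal, cervical, bladder), of which head & neck and
#' bladder contribute the two classes without a non-squamous counterpart.
#' Adrenocortical carcinoma (ACC) and uveal melanoma (UVM) are excluded as
#' small cohorts. The mapping is a reconstructed, user-overridable fixture:
#' supply a YAML file to [read_class_map()] to replace it.
#'
#' @return A [ClassMap] with 29 mapped types, 18 distinct classes and 5
#'   squamous types.
#' @export
default_class_map <- function() {
  ClassMap(
    type_to_class = c(
      # organ groups
      COAD = "colorectal",      READ = "colorectal",
      STAD = "oesophagogastric", ESCA = "oesophagogastric",
      KICH = "kidney",          KIRC = "kidney",   KIRP = "kidney",
      LIHC = "hepatobiliary",   CHOL = "hepatobiliary",
      LGG  = "brain",           GBM  = "brain",
      SARC = "soft_tissue",     MESO = "soft_tissue",
      UCEC = "gynecologic",     UCS  = "gynecologic",
      OV   = "gynecologic",     CESC = "gynecologic",
      # singleton organ classes
      BRCA = "breast",          LUAD = "lung",     LUSC = "lung",
      PAAD = "pancreas",        PCPG = "pheochromocytoma",
      PRAD = "prostate",        SKCM = "skin",     TGCT = "testis",
      THCA = "thyroid",         THYM = "thymus",
      # squamous-only organ classes
      HNSC = "head_neck",       BLCA = "bladder"),
    squamous_types = c("BLCA", "CESC", "ESCA", "HNSC", "LUSC"),
    excluded_types = c("ACC", "UVM"))
}

#' @export
print.ClassMap <- function(x, ...) {
  cat(sprintf("ClassMap: %d types -> %d classes (%d squamous types, %d excluded)\n",
              length(x$type_to_class), length(unique(x$type_to_class)),
              length(x$squamous_types), length(x$excluded_types)))
  invisible(x)
}

#' Read or write a ClassMap as YAML
#'
#' The YAML layout has three top-level keys: `type_to_class` (a mapping),
#' `squamous_types` and `excluded_types` (sequences).
#'
#' @param path Path to a YAML file.
#' @return [read_class_map()] returns a [ClassMap]; [write_class_map()]
#'   returns `path` invisibly.
#' @export
read_class_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$type_to_class)) stopf("class-map YAML lacks 'type_to_class'")
  ClassMap(type_to_class = unlist(y$type_to_class),
           squamous_types = as.character(y$squamous_types %||% character()),
           excluded_types = as.character(y$excluded_types %||% character()))
}

#' @rdname read_class_map
#' @param class_map A [ClassMap].
#' @export
write_class_map <- function(class_map, path) {
  stopifnot(inherits(class_map, "ClassMap"))
  yaml::write_yaml(list(
    type_to_class = as.list(class_map$type_to_class),
    squamous_types = class_map$squamous_types,
    excluded_types = class_map$excluded_types), path)
  invisible(path)
}
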