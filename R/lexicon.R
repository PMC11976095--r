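# Feature schema and synonym ("concept") dictionaries.
#
# Four anatomical features drive the difficulty score. Each feature has a
# fixed set of ordinal categories; each category is reached in report text
# through a set of synonym phrases. Matching is case-insensitive on
# normalized text, so all synonyms are stored lowercase.

FEATURE_IDS <- c("ANGULATION", "ROOT_COUNT", "ROOT_CURVATURE", "CANAL_RELATION")

# column names used for feature-score vectors/tables throughout the package
FEATURE_COLS <- c(
  ANGULATION = "angulation",
  ROOT_COUNT = "root_count",
  ROOT_CURVATURE = "root_curvature",
  CANAL_RELATION = "canal"
)

FEATURE_MAX <- c(angulation = 4L, root_count = 3L, root_curvature = 3L, canal = 4L)

#' Ordinal scales of the four anatomical features
#'
#' Returns the fixed scoring scales: tooth angulation (mesioangular 1,
#' horizontal 2, vertical 3, distoangular 4), number of roots (single fused 1,
#' two 2, three or more 3), root curvature (incomplete 1, straight 2,
#' dilacerated 3) and relationship to the mandibular canal (no contact 1,
#' approximation 2, contact 3, inside 4). Higher scores indicate anatomy that
#' makes extraction harder.
#'
#' @return A tibble with columns `feature_id`, `category` and `score`
#'   (14 rows: 4 + 3 + 3 + 4 categories).
#' @export
feature_scales <- function() {
  tibble::tibble(
    feature_id = rep(FEATURE_IDS, times = c(4L, 3L, 3L, 4L)),
    category = c(
      "Mesioangular", "Horizontal", "Vertical", "Distoangular",
      "Single fused root", "Two roots", "Three or more roots",
      "Incomplete roots", "Straight roots", "Dilacerated roots",
      "No contact", "Approximation", "Contact", "Inside"
    ),
    score = c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L, 4L)
  )
}

#' Build the default feature lexicon
#'
#' Constructs the built-in synonym dictionary covering all 14 feature
#' categories. The category labels and scores are fixed; the synonym
#' inventories are a clinically plausible default and can be replaced by
#' loading a custom config with [load_lexicon()].
#'
#' @return A `feature_lexicon` object: a list with elements `version` and
#'   `features` (a named list keyed by feature id; each entry is a list of
#'   categories, each with `label`, `score` and a character vector
#'   `synonyms`).
#' @examples
#' lex <- build_default_lexicon()
#' lexicon_table(lex)
#' @export
build_default_lexicon <- function() {
  lex <- list(
    version = "molardiff-default-1",
    features = list(
      ANGULATION = list(
        list(label = "Mesioangular", score = 1L, synonyms = c(
          "mesioangular", "mesioangular impaction", "mesially tilted",
          "mesial angulation", "mesially inclined", "mesioangularly positioned"
        )),
        list(label = "Horizontal", score = 2L, synonyms = c(
          "horizontal", "horizontally impacted", "horizontal angulation",
          "horizontally positioned", "horizontal impaction"
        )),
        list(label = "Vertical", score = 3L, synonyms = c(
          "vertical", "vertically oriented", "vertical angulation",
          "vertically positioned", "vertical impaction"
        )),
        list(label = "Distoangular", score = 4L, synonyms = c(
          "distoangular", "distoangular impaction", "distally tilted",
          "distal angulation", "distally inclined"
        ))
      ),
      ROOT_COUNT = list(
        list(label = "Single fused root", score = 1L, synonyms = c(
          "single fused root", "one fused root", "fused single root",
          "single root", "one root", "1 root", "a single conical root"
        )),
        list(label = "Two roots", score = 2L, synonyms = c(
          "two roots", "2 roots", "two separate roots", "double roots",
          "bifid roots"
        )),
        list(label = "Three or more roots", score = 3L, synonyms = c(
          "three or more roots", "three roots", "3 roots", "four roots",
          "4 roots", "multiple roots", "three separate roots"
        ))
      ),
      ROOT_CURVATURE = list(
        list(label = "Incomplete roots", score = 1L, synonyms = c(
          "incomplete roots", "incompletely formed roots",
          "incomplete root formation", "open apices", "immature roots"
        )),
        list(label = "Straight roots", score = 2L, synonyms = c(
          "straight roots", "straight root morphology",
          "roots without curvature", "straight and parallel roots"
        )),
        list(label = "Dilacerated roots", score = 3L, synonyms = c(
          "dilacerated roots", "dilacerated", "dilaceration",
          "root dilaceration", "severely curved roots", "curved roots"
        ))
      ),
      CANAL_RELATION = list(
        list(label = "No contact", score = 1L, synonyms = c(
          "no contact", "not in contact", "without contact",
          "distant from the mandibular canal", "clearly separated from the canal"
        )),
        list(label = "Approximation", score = 2L, synonyms = c(
          "approximation", "approximating the mandibular canal",
          "close approximation", "in close proximity to the mandibular canal",
          "approaching the mandibular canal"
        )),
        list(label = "Contact", score = 3L, synonyms = c(
          "contact", "in contact with the mandibular canal",
          "contacting the mandibular canal", "touching the mandibular canal",
          "direct contact"
        )),
        list(label = "Inside", score = 4L, synonyms = c(
          "inside the mandibular canal", "inside", "within the mandibular canal",
          "penetrating the mandibular canal", "protruding into the mandibular canal"
        ))
      )
    )
  )
  class(lex) <- "feature_lexicon"
  validate_lexicon(lex)
}

#' Flatten a lexicon to one row per synonym
#'
#' @param lex A `feature_lexicon`.
#' @return A tibble with columns `feature_id`, `category`, `score`,
#'   `synonym`, `n_tokens` (phrase length in tokens, the longest-match
#'   priority key).
#' @export
lexicon_table <- function(lex) {
  stopifnot(inherits(lex, "feature_lexicon"))
  rows <- list()
  for (fid in names(lex$features)) {
    for (cat in lex$features[[fid]]) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        feature_id = fid,
        category = cat$label,
        score = as.integer(cat$score),
        synonym = cat$synonyms
      )
    }
  }
  out <- do.call(rbind, rows)
  out$n_tokens <- vapply(
    strsplit(out$synonym, " ", fixed = TRUE), length, integer(1)
  )
  out
}

#' Validate a feature lexicon
#'
#' Enforces the structural invariants: each feature has exactly its required
#' categories with the fixed scores (unique, contiguous from 1); every
#' category has at least one non-empty lowercase synonym; no synonym phrase
#' is shared by two categories of the same feature; and within a feature any
#' phrase that is a substring of another category's phrase has strictly fewer
#' tokens, so greedy longest-match can never consume the longer phrase as the
#' shorter one.
#'
#' @param lex A candidate `feature_lexicon`.
#' @return The lexicon, invisibly classed, if valid; otherwise an error
#'   naming the offending feature/categories.
#' @export
validate_lexicon <- function(lex) {
  if (!is.list(lex) || is.null(lex$features)) {
    stop("lexicon must be a list with a 'features' element", call. = FALSE)
  }
  schema <- feature_scales()
  missing_feat <- setdiff(FEATURE_IDS, names(lex$features))
  if (length(missing_feat) > 0L) {
    stop("lexicon is missing feature(s): ", paste(missing_feat, collapse = ", "),
         call. = FALSE)
  }
  for (fid in FEATURE_IDS) {
    cats <- lex$features[[fid]]
    want <- schema[schema$feature_id == fid, ]
    labels <- vapply(cats, function(x) as.character(x$label), character(1))
    scores <- vapply(cats, function(x) as.integer(x$score), integer(1))
    miss <- setdiff(want$category, labels)
    if (length(miss) > 0L) {
      stop(fid, ": missing category '", miss[[1L]], "'", call. = FALSE)
    }
    extra <- setdiff(labels, want$category)
    if (length(extra) > 0L) {
      stop(fid, ": unknown category '", extra[[1L]], "'", call. = FALSE)
    }
    got <- scores[match(want$category, labels)]
    if (!identical(got, want$score)) {
      bad <- want$category[got != want$score][[1L]]
      stop(fid, ": category '", bad, "' has score ",
           got[want$category == bad], " but the scale requires ",
           want$score[want$category == bad], call. = FALSE)
    }
    # synonym checks within a feature
    syn_all <- character(0)
    syn_cat <- character(0)
    for (cat in cats) {
      syns <- normalize_text(as.character(cat$synonyms))
      if (length(syns) == 0L || any(!nzchar(syns))) {
        stop(fid, ": category '", cat$label,
             "' has an empty synonym after normalization", call. = FALSE)
      }
      syn_all <- c(syn_all, syns)
      syn_cat <- c(syn_cat, rep(cat$label, length(syns)))
    }
    dup <- syn_all[duplicated(syn_all)]
    for (d in unique(dup)) {
      owners <- unique(syn_cat[syn_all == d])
      if (length(owners) > 1L) {
        stop(fid, ": synonym '", d, "' is shared by categories '",
             owners[[1L]], "' and '", owners[[2L]], "'", call. = FALSE)
      }
    }
    ntok <- vapply(strsplit(syn_all, " ", fixed = TRUE), length, integer(1))
    for (i in seq_along(syn_all)) {
      inside <- grepl(syn_all[i], syn_all, fixed = TRUE) &
        syn_cat != syn_cat[i]
      if (any(inside & ntok <= ntok[i])) {
        j <- which(inside & ntok <= ntok[i])[[1L]]
        stop(fid, ": synonym '", syn_all[i], "' (", syn_cat[i],
             ") is a substring of '", syn_all[j], "' (", syn_cat[j],
             ") without lower longest-match priority", call. = FALSE)
      }
    }
  }
  class(lex) <- "feature_lexicon"
  lex
}

#' Write a lexicon to a YAML or JSON config file
#'
#' @param lex A `feature_lexicon`.
#' @param path Output path; a `.json` extension selects JSON, anything else
#'   YAML.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "feature_lexicon"))
  obj <- c(list(version = lex$version), lex$features)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' Load and validate a lexicon config file
#'
#' The config's top-level keys are the four feature ids (plus an optional
#' `version`); each feature maps to a list of `{label, score, synonyms}`
#' entries. The result must satisfy every lexicon invariant; violations are
#' reported naming the offending entry.
#'
#' @param path Path to a YAML or JSON lexicon config.
#' @return A validated `feature_lexicon`.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon config not found: ", path, call. = FALSE)
  obj <- tryCatch(
    {
      if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
      } else {
        yaml::read_yaml(path)
      }
    },
    error = function(e) {
      stop("failed to parse lexicon config '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  version <- if (!is.null(obj$version)) as.character(obj$version) else "unversioned"
  obj$version <- NULL
  # normalize each category entry
  feats <- lapply(obj, function(cats) {
    lapply(cats, function(cat) {
      if (is.null(cat$label) || is.null(cat$score) || is.null(cat$synonyms)) {
        stop("lexicon entry missing label/score/synonyms: ",
             paste(utils::capture.output(utils::str(cat)), collapse = " "),
             call. = FALSE)
      }
      list(
        label = as.character(cat$label),
        score = as.integer(cat$score),
        synonyms = normalize_text(unlist(cat$synonyms, use.names = FALSE))
      )
    })
  })
  lex <- structure(
    list(version = version, features = feats),
    class = "feature_lexicon"
  )
  validate_lexicon(lex)
}

#' @export
print.feature_lexicon <- function(x, ...) {
  tab <- lexicon_table(x)
  cat("<feature_lexicon> version:", x$version, "\n")
  cat("  ", length(unique(paste(tab$feature_id, tab$category))),
      "categories,", nrow(tab), "synonym phrases\n")
  invisible(x)
}
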