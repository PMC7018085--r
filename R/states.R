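#' Drug stimulus: clamped drug-target states
#'
#' The stimulus fixes the drug's target proteins at +1 (activated) or -1
#' (inhibited) throughout propagation. For an angiotensin
#' receptor-neprilysin inhibitor the stimulus would be
#' `stimulus(c(NEP = -1, AT1R = -1), network)`.
#'
#' @param states named numeric vector of +1/-1 values, names are proteins.
#' @param network a [signed_network()] the proteins must belong to.
#' @return an object of class `stimulus` (named numeric vector).
#' @export
stimulus <- function(states, network) {
  states <- check_states(states, network, what = "stimulus")
  structure(states, class = "stimulus")
}

#' Phenotype effector set
#'
#' Effectors are the proteins whose active (+1) / inactive (-1) states
#' molecularly define a clinical condition. Proteins not listed are neutral.
#' The `role` decides the orientation of response intensity in
#' [stratify_ensemble()]: a drug should *revert* an indication's effector
#' states and is feared to *induce* an adverse event's.
#'
#' @param name label for the phenotype (e.g. `"HF"`).
#' @param role `"indication"` or `"adverse_event"`.
#' @inheritParams stimulus
#' @return an object of class `effector_set`: list with `name`, `role`,
#'   `states`.
#' @export
effector_set <- function(name, role = c("indication", "adverse_event"),
                         states, network) {
  role <- match.arg(role)
  states <- check_states(states, network, what = paste0("effector set '", name, "'"))
  structure(list(name = name, role = role, states = states),
            class = "effector_set")
}

#' @export
print.effector_set <- function(x, ...) {
  cat(sprintf("Effector set '%s' (%s): %d proteins (%d active, %d inactive)\n",
              x$name, x$role, length(x$states),
              sum(x$states > 0), sum(x$states < 0)))
  invisible(x)
}

#' Active/inactive node restrictions
#'
#' Restrictions are the training data of the model: proteins required to end
#' up active (+1) or inactive (-1) after propagation. Each entry carries a
#' source tag (`effector`, `expression` or `literature`).
#'
#' @param states named numeric vector of +1/-1 required states.
#' @param source character vector (length 1 or `length(states)`) of source
#'   tags.
#' @param network a [signed_network()].
#' @return object of class `restriction_set`: data.frame `protein`, `state`,
#'   `source`.
#' @export
restriction_set <- function(states, source = "effector", network) {
  states <- check_states(states, network, what = "restriction set")
  source <- as.character(source)
  if (!length(source) %in% c(1L, length(states))) {
    stop_("`source` must have length 1 or length(states)")
  }
  if (!all(source %in% c("effector", "expression", "literature"))) {
    stop_("restriction source tags must be effector/expression/literature")
  }
  structure(
    data.frame(protein = names(states), state = unname(states),
               source = source, stringsAsFactors = FALSE),
    class = c("restriction_set", "data.frame")
  )
}

#' Merge restriction sets
#'
#' @param ... `restriction_set` objects.
#' @return a single `restriction_set`; contradictory duplicates error.
#' @export
merge_restrictions <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "restriction_set")))
  df <- do.call(rbind, lapply(parts, as.data.frame))
  agg <- tapply(df$state, df$protein, function(s) length(unique(s)))
  if (any(agg > 1)) {
    stop_("contradictory restriction for protein '",
          names(agg)[agg > 1][1L], "'")
  }
  df <- df[!duplicated(df$protein), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("restriction_set", "data.frame"))
}

check_states <- function(states, network, what) {
  if (length(states) == 0L) stop_(what, " must be non-empty")
  if (is.null(names(states)) || any(names(states) == "")) {
    stop_(what, ": states must be a named vector")
  }
  states <- vapply(states, as.numeric, 0)
  if (!all(states %in% c(-1, 1))) stop_(what, ": states must be +1 or -1")
  dup <- unique(names(states)[duplicated(names(states))])
  if (length(dup)) {
    for (p in dup) {
      if (length(unique(states[names(states) == p])) > 1L) {
        stop_(what, ": protein '", p, "' mapped to both +1 and -1")
      }
    }
    states <- states[!duplicated(names(states))]
  }
  if (!missing(network) && !is.null(network)) {
    stopifnot(inherits(network, "signed_network"))
    absent <- setdiff(names(states), network$nodes)
    if (length(absent)) {
      stop_(what, ": protein(s) not in network: ",
            paste(head(absent, 5L), collapse = ", "))
    }
  }
  states
}

#' Read a two-column protein-state TSV
#'
#' Rows of `protein<TAB>state` (header line required) with state one of
#' `+1`, `-1`, `active`, `inactive`, `activation`, `inhibition`. The typed
#' wrapper (stimulus / effector set / restriction set) is chosen by `as=`;
#' name and role come from the caller, never the file.
#'
#' @param path file path.
#' @param network a [signed_network()] used to validate protein names.
#' @param as one of `"stimulus"`, `"effectors"`, `"restrictions"`.
#' @param name,role passed to [effector_set()] when `as = "effectors"`.
#' @param unknown policy for proteins absent from the network: `"fail"`
#'   (default) or `"drop"` (drop with a warning listing them).
#' @return the typed state object; dropped proteins (if any) are attached as
#'   attribute `"dropped"`.
#' @export
read_states <- function(path, network,
                        as = c("stimulus", "effectors", "restrictions"),
                        name = "states", role = "indication",
                        unknown = c("fail", "drop")) {
  as <- match.arg(as)
  unknown <- match.arg(unknown)
  if (!file.exists(path)) stop_("state file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_("state file needs two columns: protein, state")
  if (nrow(df) == 0L) stop_("state file is empty: ", path)
  prot <- as.character(df[[1L]])
  st <- sign_token(df[[2L]], where = paste0(" in ", path))
  dropped <- character(0)
  if (unknown == "drop") {
    absent <- !(prot %in% network$nodes)
    if (any(absent)) {
      dropped <- prot[absent]
      warning("dropping ", length(dropped),
              " protein(s) absent from the network: ",
              paste(head(dropped, 5L), collapse = ", "), call. = FALSE)
      prot <- prot[!absent]
      st <- st[!absent]
      if (!length(prot)) stop_("no proteins left after dropping unknowns")
    }
  }
  states <- st
  names(states) <- prot
  out <- switch(as,
    stimulus = stimulus(states, network),
    effectors = effector_set(name, role, states, network),
    restrictions = restriction_set(states, network = network)
  )
  attr(out, "dropped") <- dropped
  out
}

#' Write protein states as a two-column TSV
#'
#' @param states a `stimulus`, `effector_set` or `restriction_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(states, path) {
  if (inherits(states, "effector_set")) states <- states$states
  if (inherits(states, "restriction_set")) {
    df <- data.frame(protein = states$protein, state = states$state)
  } else {
    df <- data.frame(protein = names(states), state = as.numeric(states))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
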