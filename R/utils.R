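# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop with a classed condition so callers can test error classes
twv_abort <- function(msg, class) {
  abort(msg, class = c(class, "twaveshape_error"))
}

assert_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    twv_abort(
      sprintf("`%s` must be a finite number %s %s, got %s",
              name, if (strict) ">" else ">=", lower,
              paste(format(x), collapse = ", ")),
      "twv_bad_argument"
    )
  }
  invisible(x)
}

# coerce a trace argument (twv_beat, twv_window, or data frame with
# time_ms / mv columns) to a plain tibble(time_ms, mv)
as_trace <- function(x) {
  if (inherits(x, "twv_beat")) return(x$trace)
  if (is.data.frame(x)) {
    if (!all(c("time_ms", "mv") %in% names(x))) {
      twv_abort("trace must have columns `time_ms` and `mv`", "twv_bad_trace")
    }
    return(as_tibble(x[, c("time_ms", "mv")]))
  }
  twv_abort("cannot interpret input as a beat trace", "twv_bad_trace")
}

# tidy configurations -> k x 2 x n array, preserving ids and groups
config_array <- function(configs, landmarks = NULL) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    k <- dim(configs)[1]
    return(list(
      arr = configs,
      ids = dimnames(configs)[[3]] %||% as.character(seq_len(dim(configs)[3])),
      groups = NULL,
      landmarks = dimnames(configs)[[1]] %||% as.character(seq_len(k))
    ))
  }
  if (!is.data.frame(configs)) {
    twv_abort("configurations must be a tidy data frame or a k x 2 x n array",
              "twv_bad_configs")
  }
  nm <- names(configs)
  id_col <- intersect(c("case_id", "config_id", "id"), nm)[1]
  if (is.na(id_col) || !all(c("landmark", "x", "y") %in% nm)) {
    twv_abort(
      "tidy configurations need columns case_id (or config_id), landmark, x, y",
      "twv_bad_configs"
    )
  }
  lms <- landmarks %||% unique(as.character(configs$landmark))
  ids <- unique(as.character(configs[[id_col]]))
  k <- length(lms)
  arr <- array(NA_real_, dim = c(k, 2, length(ids)),
               dimnames = list(lms, c("x", "y"), ids))
  for (i in seq_along(ids)) {
    sub <- configs[configs[[id_col]] == ids[i], ]
    m <- match(lms, as.character(sub$landmark))
    if (anyNA(m)) {
      twv_abort(sprintf("configuration `%s` is missing landmarks", ids[i]),
                "twv_bad_configs")
    }
    arr[, 1, i] <- sub$x[m]
    arr[, 2, i] <- sub$y[m]
  }
  groups <- NULL
  if ("group" %in% nm) {
    groups <- vapply(ids, function(id) {
      as.character(configs$group[configs[[id_col]] == id][1])
    }, character(1))
  }
  list(arr = arr, ids = ids, groups = groups, landmarks = lms)
}

array_to_tidy <- function(arr, ids, groups = NULL) {
  k <- dim(arr)[1]
  lms <- dimnames(arr)[[1]] %||% as.character(seq_len(k))
  out <- purrr::map(seq_along(ids), function(i) {
    tibble(
      case_id = ids[i],
      landmark = lms,
      x = arr[, 1, i],
      y = arr[, 2, i]
    )
  }) %>% list_rbind()
  if (!is.null(groups)) {
    out <- left_join(out, tibble(case_id = ids, group = groups), by = "case_id")
    out <- out[, c("case_id", "group", "landmark", "x", "y")]
  }
  out
}
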