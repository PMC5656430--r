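#' Cross-animal involvement rule
#'
#' A neuron is considered involved in a behavior if its coherence magnitude
#' exceeds the 95\% null threshold in at least \code{min_animals} of the
#' animals in which it was measured (4 of 6 by default). For bilaterally
#' symmetric behaviors (swimming, crawling), both members of a homologous
#' pair are included if, and only if, at least one member exceeds the
#' stricter 97.5\% threshold under the same cross-animal rule. Neurons
#' measured in fewer than \code{min_animals} animals are flagged
#' undetermined. The per-behavior booleans are reduced to a Venn tabulation
#' over the three behaviors.
#'
#' @param results data frame with one row per (animal, neuron, behavior):
#'   columns \code{animal}, \code{neuron_id}, \code{behavior}
#'   ("bend"/"swim"/"crawl"), \code{magnitude}, \code{k} (taper count used).
#' @param map a \code{canonical_map} supplying homolog pairing.
#' @param min_animals minimum number of animals above threshold (default 4).
#' @param n_animals nominal number of animals (default 6); must be >=
#'   \code{min_animals}.
#' @param alpha individual involvement level (default 0.05).
#' @param pair_alpha homolog-completion level (default 0.025).
#' @param symmetric behaviors subject to homolog completion.
#' @return An \code{involvement_map}: list with \code{table} (per neuron:
#'   involvement per behavior, \code{undetermined} flags, combination class)
#'   and \code{venn} (counts per region over the three behaviors, including
#'   \code{"none"}; undetermined neurons appear in no region).
#' @export
involvement <- function(results, map, min_animals = 4L, n_animals = 6L,
                        alpha = 0.05, pair_alpha = 0.025,
                        symmetric = c("swim", "crawl")) {
  if (min_animals > n_animals) stop_input("min_animals must be <= n_animals")
  need <- c("animal", "neuron_id", "behavior", "magnitude", "k")
  if (!all(need %in% names(results))) {
    stop_input("results needs columns: ", paste(need, collapse = ", "))
  }
  behaviors <- sort(unique(results$behavior))
  neurons <- unique(results$neuron_id)
  homolog <- stats::setNames(map$homolog_id, map$id)

  passes <- function(sub, a) {
    thr <- null_threshold(sub$k, a)
    sum(sub$magnitude > thr)
  }
  tab <- expand.grid(neuron_id = neurons, behavior = behaviors,
                     stringsAsFactors = FALSE)
  tab$n_measured <- 0L
  tab$n_above <- 0L
  tab$n_above_pair <- 0L
  for (i in seq_len(nrow(tab))) {
    sub <- results[results$neuron_id == tab$neuron_id[i] &
                   results$behavior == tab$behavior[i], , drop = FALSE]
    sub <- sub[!duplicated(sub$animal), , drop = FALSE]
    tab$n_measured[i] <- nrow(sub)
    tab$n_above[i] <- passes(sub, alpha)
    tab$n_above_pair[i] <- passes(sub, pair_alpha)
  }
  tab$undetermined <- tab$n_measured < min_animals
  tab$involved <- !tab$undetermined & tab$n_above >= min_animals
  pair_pass <- !tab$undetermined & tab$n_above_pair >= min_animals
  # homolog completion for symmetric behaviors
  for (b in intersect(symmetric, behaviors)) {
    sel <- tab$behavior == b
    pp <- stats::setNames(pair_pass[sel], tab$neuron_id[sel])
    und <- stats::setNames(tab$undetermined[sel], tab$neuron_id[sel])
    for (id in names(pp)) {
      hom <- homolog[[id]]
      if (!is.null(hom) && !is.na(hom) && hom %in% names(pp)) {
        if ((pp[[id]] || pp[[hom]])) {
          tab$involved[sel & tab$neuron_id %in% c(id, hom) &
                         !tab$undetermined] <- TRUE
        }
      }
    }
  }
  wide <- stats::reshape(
    tab[c("neuron_id", "behavior", "involved", "undetermined")],
    idvar = "neuron_id", timevar = "behavior", direction = "wide")
  inv_cols <- paste0("involved.", behaviors)
  und_cols <- paste0("undetermined.", behaviors)
  wide$undetermined <- apply(wide[und_cols], 1, any)
  combo <- apply(wide[inv_cols], 1, function(z) {
    z[is.na(z)] <- FALSE
    if (!any(z)) "none" else paste(behaviors[z], collapse = "+")
  })
  wide$combination <- ifelse(wide$undetermined, NA_character_, combo)
  venn <- table(wide$combination[!wide$undetermined])
  structure(list(table = wide, venn = venn, behaviors = behaviors,
                 min_animals = min_animals, alpha = alpha,
                 pair_alpha = pair_alpha),
            class = "involvement_map")
}

#' @export
print.involvement_map <- function(x, ...) {
  cat(sprintf("<involvement_map> %d neurons, rule: >= %d animals above the %g%% threshold\n",
              nrow(x$table), x$min_animals, 100 * (1 - x$alpha)))
  print(x$venn)
  invisible(x)
}

#' Write an involvement map as JSON keyed by neuron id
#' @param im an \code{involvement_map}.
#' @param path file path.
#' @export
write_involvement <- function(im, path) {
  tab <- im$table
  lst <- stats::setNames(lapply(seq_len(nrow(tab)), function(i) {
    as.list(tab[i, setdiff(names(tab), "neuron_id")])
  }), tab$neuron_id)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
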