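# French Snowball stemmer (classic variant), implemented from the published
# algorithm: vowel marking, RV/R1/R2 regions, standard-suffix step, the two
# verb-suffix steps, residual-suffix step, undoubling and accent removal.

.fr_vowels <- c("a", "e", "i", "o", "u", "y",
                "â", "à", "ë", "é", "ê", "è",
                "ï", "î", "ô", "û", "ù")

.is_vowel <- function(ch) ch %in% .fr_vowels

# u/i between vowels, y next to a vowel and u after q are marked upper case so
# that later steps treat them as consonants. Neighbours are taken from the
# original (unmarked) word.
.fr_mark <- function(chars) {
  n <- length(chars)
  if (n == 0L) return(chars)
  out <- chars
  for (j in seq_len(n)) {
    ch <- chars[j]
    prev_v <- j > 1L && .is_vowel(chars[j - 1L])
    next_v <- j < n && .is_vowel(chars[j + 1L])
    if (ch == "u") {
      if ((prev_v && next_v) || (j > 1L && chars[j - 1L] == "q")) out[j] <- "U"
    } else if (ch == "i") {
      if (prev_v && next_v) out[j] <- "I"
    } else if (ch == "y") {
      if (prev_v || next_v) out[j] <- "Y"
    }
  }
  out
}

# Region start indices (1-based position of the first character of the region;
# n + 1 when the region is empty).
.fr_regions <- function(chars) {
  n <- length(chars)
  none <- n + 1L
  rv <- none
  if (n >= 3L) {
    pre3 <- paste(chars[1:3], collapse = "")
    if ((.is_vowel(chars[1L]) && .is_vowel(chars[2L])) ||
        pre3 %in% c("par", "col", "tap")) {
      rv <- 4L
    }
  }
  if (rv == none && n >= 2L) {
    for (j in 2:n) {
      if (.is_vowel(chars[j])) { rv <- j + 1L; break }
    }
  }
  r1 <- none
  if (n >= 2L) {
    for (j in 2:n) {
      if (!.is_vowel(chars[j]) && .is_vowel(chars[j - 1L])) { r1 <- j + 1L; break }
    }
  }
  r2 <- none
  if (r1 < none && r1 + 1L <= n) {
    for (j in (r1 + 1L):n) {
      if (!.is_vowel(chars[j]) && .is_vowel(chars[j - 1L])) { r2 <- j + 1L; break }
    }
  }
  list(rv = rv, r1 = r1, r2 = r2)
}

.suffix_start <- function(word, suf) {
  nw <- nchar(word); ns <- nchar(suf)
  if (ns > nw) return(0L)
  if (substring(word, nw - ns + 1L, nw) == suf) nw - ns + 1L else 0L
}

.drop_tail <- function(word, k) substring(word, 1L, nchar(word) - k)

.step1_suffixes <- local({
  tab <- list(
    g1 = c("ances", "iqUes", "ismes", "ables", "istes",
           "ance", "iqUe", "isme", "able", "iste", "eux"),
    g2 = c("atrices", "ateurs", "ations", "atrice", "ateur", "ation"),
    g3 = c("logies", "logie"),
    g4 = c("usions", "utions", "usion", "ution"),
    g5 = c("ences", "ence"),
    g6 = c("ements", "ement"),
    g7 = c("ités", "ité"),
    g8 = c("ives", "ifs", "ive", "if"),
    g9 = "eaux",
    g10 = "aux",
    g11 = c("euses", "euse"),
    g12 = c("issements", "issement"),
    g13 = "amment",
    g14 = "emment",
    g15 = c("ments", "ment")
  )
  suf <- unlist(tab, use.names = FALSE)
  grp <- rep(names(tab), lengths(tab))
  ord <- order(-nchar(suf))
  list(suf = suf[ord], grp = grp[ord])
})

# Returns list(word, changed, ment) where `ment` flags removal of one of the
# adverbial ment-family suffixes (this re-enables the verb-suffix steps).
.fr_step1 <- function(word, rv, r1, r2) {
  suf <- .step1_suffixes$suf
  grp <- .step1_suffixes$grp
  hit <- 0L
  for (i in seq_along(suf)) {
    p <- .suffix_start(word, suf[i])
    if (p > 0L) { hit <- i; break }
  }
  if (hit == 0L) return(list(word = word, changed = FALSE, ment = FALSE))
  s <- suf[hit]; g <- grp[hit]
  p <- .suffix_start(word, s)
  w <- word
  changed <- FALSE
  ment <- FALSE
  in_r2 <- p >= r2
  in_r1 <- p >= r1
  in_rv <- p >= rv
  if (g == "g1") {
    if (in_r2) { w <- .drop_tail(w, nchar(s)); changed <- TRUE }
  } else if (g == "g2") {
    if (in_r2) {
      w <- .drop_tail(w, nchar(s)); changed <- TRUE
      q <- .suffix_start(w, "ic")
      if (q > 0L) {
        if (q >= r2) w <- .drop_tail(w, 2L) else w <- paste0(.drop_tail(w, 2L), "iqU")
      }
    }
  } else if (g == "g3") {
    if (in_r2) { w <- paste0(.drop_tail(w, nchar(s)), "log"); changed <- TRUE }
  } else if (g == "g4") {
    if (in_r2) { w <- paste0(.drop_tail(w, nchar(s)), "u"); changed <- TRUE }
  } else if (g == "g5") {
    if (in_r2) { w <- paste0(.drop_tail(w, nchar(s)), "ent"); changed <- TRUE }
  } else if (g == "g6") {
    if (in_rv) {
      w <- .drop_tail(w, nchar(s)); changed <- TRUE
      q <- .suffix_start(w, "iv")
      if (q > 0L && q >= r2) {
        w <- .drop_tail(w, 2L)
        q2 <- .suffix_start(w, "at")
        if (q2 > 0L && q2 >= r2) w <- .drop_tail(w, 2L)
      } else {
        q <- .suffix_start(w, "eus")
        if (q > 0L) {
          if (q >= r2) w <- .drop_tail(w, 3L)
          else if (q >= r1) w <- paste0(.drop_tail(w, 3L), "eux")
        } else {
          qa <- .suffix_start(w, "abl"); qi <- .suffix_start(w, "iqU")
          if (qa > 0L && qa >= r2) {
            w <- .drop_tail(w, 3L)
          } else if (qi > 0L && qi >= r2) {
            w <- .drop_tail(w, 3L)
          } else {
            q1 <- .suffix_start(w, "ièr"); q2 <- .suffix_start(w, "Ièr")
            if (q1 > 0L && q1 >= rv) w <- paste0(.drop_tail(w, 3L), "i")
            else if (q2 > 0L && q2 >= rv) w <- paste0(.drop_tail(w, 3L), "i")
          }
        }
      }
    }
  } else if (g == "g7") {
    if (in_r2) {
      w <- .drop_tail(w, nchar(s)); changed <- TRUE
      q <- .suffix_start(w, "abil")
      if (q > 0L) {
        if (q >= r2) w <- .drop_tail(w, 4L) else w <- paste0(.drop_tail(w, 4L), "abl")
      } else {
        q <- .suffix_start(w, "ic")
        if (q > 0L) {
          if (q >= r2) w <- .drop_tail(w, 2L) else w <- paste0(.drop_tail(w, 2L), "iqU")
        } else {
          q <- .suffix_start(w, "iv")
          if (q > 0L && q >= r2) w <- .drop_tail(w, 2L)
        }
      }
    }
  } else if (g == "g8") {
    if (in_r2) {
      w <- .drop_tail(w, nchar(s)); changed <- TRUE
      q <- .suffix_start(w, "at")
      if (q > 0L && q >= r2) {
        w <- .drop_tail(w, 2L)
        q <- .suffix_start(w, "ic")
        if (q > 0L) {
          if (q >= r2) w <- .drop_tail(w, 2L) else w <- paste0(.drop_tail(w, 2L), "iqU")
        }
      }
    }
  } else if (g == "g9") {
    w <- paste0(.drop_tail(w, 4L), "eau"); changed <- TRUE
  } else if (g == "g10") {
    if (in_r1) { w <- paste0(.drop_tail(w, 3L), "al"); changed <- TRUE }
  } else if (g == "g11") {
    if (in_r2) { w <- .drop_tail(w, nchar(s)); changed <- TRUE }
    else if (in_r1) { w <- paste0(.drop_tail(w, nchar(s)), "eux"); changed <- TRUE }
  } else if (g == "g12") {
    if (in_r1 && p > 1L && !.is_vowel(substring(w, p - 1L, p - 1L))) {
      w <- .drop_tail(w, nchar(s)); changed <- TRUE
    }
  } else if (g == "g13") {
    if (in_rv) { w <- paste0(.drop_tail(w, 6L), "ant"); changed <- TRUE; ment <- TRUE }
  } else if (g == "g14") {
    if (in_rv) { w <- paste0(.drop_tail(w, 6L), "ent"); changed <- TRUE; ment <- TRUE }
  } else if (g == "g15") {
    if (p > 1L && p - 1L >= rv && .is_vowel(substring(w, p - 1L, p - 1L))) {
      w <- .drop_tail(w, nchar(s)); changed <- TRUE; ment <- TRUE
    }
  }
  list(word = w, changed = changed, ment = ment)
}

.step2a_suffixes <- local({
  s <- c("îmes", "ît", "îtes", "i", "ie", "ies", "ir", "ira",
         "irai", "iraIent", "irais", "irait", "iras", "irent", "irez", "iriez",
         "irions", "irons", "iront", "is", "issaIent", "issais", "issait",
         "issant", "issante", "issantes", "issants", "isse", "issent", "isses",
         "issez", "issiez", "issions", "issons", "it")
  s[order(-nchar(s))]
})

.fr_step2a <- function(word, rv) {
  for (s in .step2a_suffixes) {
    p <- .suffix_start(word, s)
    if (p > 0L && p >= rv) {
      if (p > 1L && p - 1L >= rv &&
          !.is_vowel(substring(word, p - 1L, p - 1L))) {
        return(list(word = .drop_tail(word, nchar(s)), changed = TRUE))
      }
      return(list(word = word, changed = FALSE))
    }
  }
  list(word = word, changed = FALSE)
}

.step2b_suffixes <- local({
  b2 <- c("é", "ée", "ées", "és", "èrent", "er",
          "era", "erai", "eraIent", "erais", "erait", "eras", "erez", "eriez",
          "erions", "erons", "eront", "ez", "iez")
  b3 <- c("âmes", "ât", "âtes", "a", "ai", "aIent", "ais",
          "ait", "ant", "ante", "antes", "ants", "as", "asse", "assent",
          "asses", "assiez", "assions")
  suf <- c("ions", b2, b3)
  grp <- c("ions", rep("e_grp", length(b2)), rep("a_grp", length(b3)))
  ord <- order(-nchar(suf))
  list(suf = suf[ord], grp = grp[ord])
})

.fr_step2b <- function(word, rv, r2) {
  suf <- .step2b_suffixes$suf
  grp <- .step2b_suffixes$grp
  for (i in seq_along(suf)) {
    p <- .suffix_start(word, suf[i])
    if (p > 0L && p >= rv) {
      g <- grp[i]
      if (g == "ions") {
        if (p >= r2) return(list(word = .drop_tail(word, 4L), changed = TRUE))
        return(list(word = word, changed = FALSE))
      }
      w <- .drop_tail(word, nchar(suf[i]))
      if (g == "a_grp") {
        q <- nchar(w)
        if (q >= 1L && substring(w, q, q) == "e" && q >= rv) w <- .drop_tail(w, 1L)
      }
      return(list(word = w, changed = TRUE))
    }
  }
  list(word = word, changed = FALSE)
}

.fr_step4 <- function(word, rv, r2) {
  n <- nchar(word)
  if (n >= 2L && substring(word, n, n) == "s") {
    prev <- substring(word, n - 1L, n - 1L)
    if (!prev %in% c("a", "i", "o", "u", "è", "s")) {
      word <- .drop_tail(word, 1L)
    }
  }
  cand <- list(
    list(s = "ière", act = "i"), list(s = "Ière", act = "i"),
    list(s = "ion", act = "ion"),
    list(s = "ier", act = "i"), list(s = "Ier", act = "i"),
    list(s = "e", act = "del"), list(s = "ë", act = "gue")
  )
  cand <- cand[order(-vapply(cand, function(x) nchar(x$s), 1L))]
  for (cc in cand) {
    p <- .suffix_start(word, cc$s)
    if (p > 0L && p >= rv) {
      if (cc$act == "ion") {
        if (p >= r2 && p > 1L && p - 1L >= rv &&
            substring(word, p - 1L, p - 1L) %in% c("s", "t")) {
          return(.drop_tail(word, 3L))
        }
        return(word)
      }
      if (cc$act == "i") return(paste0(.drop_tail(word, nchar(cc$s)), "i"))
      if (cc$act == "del") return(.drop_tail(word, 1L))
      if (cc$act == "gue") {
        if (p > 2L && substring(word, p - 2L, p - 1L) == "gu") {
          return(.drop_tail(word, 1L))
        }
        return(word)
      }
    }
  }
  word
}

.fr_step5 <- function(word) {
  for (s in c("enn", "onn", "ett", "ell", "eill")) {
    if (.suffix_start(word, s) > 0L) return(.drop_tail(word, 1L))
  }
  word
}

.fr_step6 <- function(word) {
  sub("[éè]([^aeiouyâàëéêèïîôûù]+)$",
      "e\\1", word)
}

.stem_one_fr <- function(word) {
  if (nchar(word) <= 2L) return(word)
  chars <- .fr_mark(strsplit(word, "", fixed = TRUE)[[1L]])
  reg <- .fr_regions(chars)
  w <- paste(chars, collapse = "")
  rv <- reg$rv; r1 <- reg$r1; r2 <- reg$r2

  s1 <- .fr_step1(w, rv, r1, r2)
  w <- s1$word
  altered <- s1$changed
  ch2a <- FALSE; ch2b <- FALSE
  if (!s1$changed || s1$ment) {
    s2a <- .fr_step2a(w, rv)
    w <- s2a$word
    ch2a <- s2a$changed
    if (!ch2a) {
      s2b <- .fr_step2b(w, rv, r2)
      w <- s2b$word
      ch2b <- s2b$changed
    }
  }
  altered <- altered || ch2a || ch2b
  if (altered) {
    n <- nchar(w)
    last <- substring(w, n, n)
    if (last == "Y") w <- paste0(.drop_tail(w, 1L), "i")
    else if (last == "ç") w <- paste0(.drop_tail(w, 1L), "c")
  } else {
    w <- .fr_step4(w, rv, r2)
  }
  w <- .fr_step5(w)
  w <- .fr_step6(w)
  chartr("UIY", "uiy", w)
}

#' Stem French words with the Snowball algorithm
#'
#' Reduces inflected French word forms to stems using the Snowball French
#' stemming algorithm (the stemmer family descended from Porter's algorithm).
#' Words of two characters or fewer, and words containing no letters, are
#' returned unchanged.
#'
#' @param words character vector of lower-case words (no punctuation).
#' @return character vector of stems, same length as `words`.
#' @examples
#' stem_french(c("effets", "secondaires", "rapidement"))
#' @export
stem_french <- function(words) {
  if (length(words) == 0L) return(character(0))
  uq <- unique(words)
  stems <- vapply(uq, .stem_one_fr, character(1), USE.NAMES = FALSE)
  stems[match(words, uq)]
}
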