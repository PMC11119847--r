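# Shared fixtures, built in code at test time.

ZOPOLRESTAT_SMILES <- "OC(=O)Cc1nn(Cc2nc3cc(ccc3s2)C(F)(F)F)c(=O)c2ccccc21"

# canonical SMILES of the four fragments expected from the reference
# inhibitor's decomposition
REFERENCE_FRAGMENT_SMILES <- c("FC(F)F", "OC=O", "Cc1nc2c(s1)cccc2",
                               "O=c1[nH]nc(c2c1cccc2)C")

# a fragmentation of n-butane with native 3D coordinates (two rigid
# ethane fragments) -- the smallest multi-fragment chemistry fixture
butaneFragmentation <- function() {
  decompose(quboDock:::.idealAlkane(4))
}

hexaneFragmentation <- function() {
  decompose(quboDock:::.idealAlkane(6))
}

# rigid-transform helpers
translatePose <- function(xyz, v) sweep(xyz, 2, v, "+")

rotatePoseZ <- function(xyz, angleDeg, center = colMeans(xyz)) {
  a <- angleDeg * pi / 180
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
}

# a random abstract QUBO instance (no chemistry): K fragment groups with
# m_k placements each, random scores, random clash/conn pair terms
randomQuboInstance <- function(K = 3, mMax = 3, pClash = 0.2, pConn = 0.2) {
  sizes <- sample(seq_len(mMax), K, replace = TRUE)
  groups <- split(seq_len(sum(sizes)), rep(seq_len(K), sizes))
  n <- sum(sizes)
  frag <- rep(seq_len(K), sizes)
  terms <- NULL
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (frag[i] == frag[j]) next
        u <- runif(1)
        if (u < pClash) {
          terms <- rbind(terms, data.frame(i = i, j = j, clash = 1L,
                                           conn = 0L))
        } else if (u < pClash + pConn) {
          terms <- rbind(terms, data.frame(i = i, j = j, clash = 0L,
                                           conn = -1L))
        }
      }
    }
  }
  quboFromTerms(dG = round(runif(n, -8, -0.5), 3), groups = groups,
                terms = terms)
}

randomBinary <- function(n) sample(0:1, n, replace = TRUE)
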