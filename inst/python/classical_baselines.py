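"""Subprocess bridge to scikit-learn for the random-forest and RBF-SVM
baselines (no R implementation is assumed installed).

Usage: python classical_baselines.py {rf|svm} WORKDIR N_PRED SEED

WORKDIR/train.csv holds label,features (no header); predN.csv hold
feature rows; predictions are written to WORKDIR/outN.txt, one 0-based
class id per line.
"""
import sys

import numpy as np
from sklearn.ensemble import RandomForestClassifier
from sklearn.svm import SVC


def main():
    method, workdir, n_pred, seed = sys.argv[1:5]
    n_pred, seed = int(n_pred), int(seed)
    train = np.loadtxt(f"{workdir}/train.csv", delimiter=",", ndmin=2)
    y, X = train[:, 0].astype(int), train[:, 1:]
    if method == "rf":
        model = RandomForestClassifier(n_estimators=100, random_state=seed)
    elif method == "svm":
        model = SVC(kernel="rbf", C=1.0, random_state=seed)
    else:
        raise SystemExit(f"unknown method: {method}")
    model.fit(X, y)
    for i in range(1, n_pred + 1):
        P = np.loadtxt(f"{workdir}/pred{i}.csv", delimiter=",", ndmin=2)
        np.savetxt(f"{workdir}/out{i}.txt", model.predict(P), fmt="%d")


if __name__ == "__main__":
    main()
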