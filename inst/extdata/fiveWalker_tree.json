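{"format":"mbcmsm-tree","version":1,"nCycles":5,"nWalkers":5,"tauWE":1,"states":[[2,3,5,6,9],[3,2,6,5,8],[2,4,5,6,9],[3,3,6,7,8],[2,4,5,6,9]],"weights":[[0.2,0.2,0.2,0.2,0.2],[0.2,0.2,0.2,0.2,0.2],[0.2,0.2,0.2,0.2,0.2],[0.2,0.2,0.2,0.2,0.2],[0.2,0.2,0.2,0.2,0.2]],"parents":[[0,0,0,0,0],[1,2,3,4,5],[1,1,3,4,5],[1,2,3,3,5],[1,2,3,4,5]],"cloneFrac":[[1,1,1,1,1],[1,1,1,1,1],[0.5,0.5,1,1,1],[1,1,0.5,0.5,1],[1,1,1,1,1]],"squashes":[{"cycle":2,"walker":2,"frac":1,"into":1},{"cycle":3,"walker":4,"frac":1,"into":3}],"fates":[["CONTINUED","CONTINUED","CONTINUED","CONTINUED","CONTINUED"],["KEPT_MERGE(2)+CLONED(2)","SQUASHED(1)","CONTINUED","CONTINUED","CONTINUED"],["CONTINUED","CONTINUED","KEPT_MERGE(4)+CLONED(2)","SQUASHED(3)","CONTINUED"],["CONTINUED","CONTINUED","CONTINUED","CONTINUED","CONTINUED"],["CONTINUED","CONTINUED","CONTINUED","CONTINUED","CONTINUED"]],"meta":{"nStates":10,"fixture":"fiveWalker"}}
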