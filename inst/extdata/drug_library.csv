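name,INa_ic50,INa_n,ICaL_ic50,ICaL_n,Ito_ic50,Ito_n,IKr_ic50,IKr_n,IKs_ic50,IKs_n,IK1_ic50,IK1_n,INaCa_ic50,INaCa_n,INaK_ic50,INaK_n,eftpc,true_class
amiodarone,4.577,0.7,1.281,0.6,3.758,0.4,0.941,0.6,13.390,1,inf,1,inf,1,inf,1,0.778,high
bepridil,2.929,1.2,2.806,0.6,inf,1,0.149,0.9,inf,1,inf,1,inf,1,inf,1,0.0315,high
diltiazem,inf,1,0.112,0.7,inf,1,6.569,0.8,inf,1,inf,1,inf,1,inf,1,0.1275,low
dofetilide,inf,1,inf,1,0.018,1,0.001,0.6,inf,1,inf,1,inf,1,inf,1,0.0021,high
flecainide,6.677,1.9,25.599,1.4,9.266,0.7,0.692,0.8,inf,1,inf,1,inf,1,inf,1,0.7529,high
mibefradil,5.866,1,0.652,1.1,inf,1,0.307,0.9,inf,1,33.802,1,inf,1,inf,1,0.0106,low
moxifloxacin,922.727,1,inf,1,inf,1,93.041,0.6,50.321,1,inf,1,inf,1,inf,1,3.5625,high
quinidine,18.815,1,inf,1,3.847,1.3,0.343,1,4.899,1.4,inf,1,inf,1,inf,1,0.8429,high
sotalol,inf,1,5976.923,1,inf,1,86.369,0.9,4762.745,1,3340.415,1,inf,1,inf,1,14.6864,borderline
verapamil,inf,1,0.202,1.1,inf,1,0.499,1.1,inf,1,inf,1,inf,1,inf,1,0.045,low
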