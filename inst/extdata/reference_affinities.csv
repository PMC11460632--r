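oligo,modification,protein,method,kd_uM,kd_err_uM,N,dG,dH,mTdS,hc_substrate
HA4,,CD44_HABD,MST,2200,1,,,,,No
HA4,2AA,CD44_HABD,MST,1200,650,,,,,No
HA4,3AA,CD44_HABD,MST,845,350,,,,,No
HA4,4AA,CD44_HABD,MST,488,141,,,,,Yes
HA6,,Link_TSG6,ITC,1.09,0.04,1.04,-8.13,-8.29,0.162,No
HA6,2AA,Link_TSG6,ITC,0.57,0.04,1.03,-8.50,-7.84,-0.66,Yes
HA6,3AA,Link_TSG6,ITC,0.50,0.09,1.05,-8.61,-6.30,-2.21,No
HA6,4AA,Link_TSG6,ITC,0.70,0.09,1.02,-8.40,-7.57,-0.83,Yes
HA6,2A4MBA,Link_TSG6,ITC,0.46,0.02,1.00,-8.64,-10.07,1.44,Yes
HA6,3APY,Link_TSG6,ITC,2.24,0.68,0.93,-7.77,-7.82,0.04,Yes
HA6,4AI,Link_TSG6,ITC,1.42,0.06,0.97,-7.98,-7.16,-0.82,No
HA6,5AI,Link_TSG6,ITC,0.68,0.08,1.03,-8.43,-7.46,-0.96,No
HA6,,CD44_HABD,MST,103,1,,,,,No
HA6,2AA,CD44_HABD,MST,181,3,,,,,Yes
HA6,3AA,CD44_HABD,MST,896,225,,,,,No
HA6,4AA,CD44_HABD,MST,253,3,,,,,Yes
HA6,2A4MBA,CD44_HABD,MST,198,29,,,,,Yes
HA6,3APY,CD44_HABD,MST,113,6,,,,,Yes
HA6,4AI,CD44_HABD,MST,369,43,,,,,No
HA6,5AI,CD44_HABD,MST,77,12,,,,,No
HA8,,Link_TSG6,ITC,0.31,0.02,0.98,-8.89,-7.26,-1.63,Yes
HA8,2AA,Link_TSG6,ITC,1.97,0.38,1.06,-7.83,-12.55,4.69,Yes
HA8,3AA,Link_TSG6,ITC,0.29,0.05,1.05,-8.95,-8.53,-0.60,Yes
HA8,4AA,Link_TSG6,ITC,0.74,0.05,0.86,-8.37,-11.53,3.17,Yes
HA8,2A4MBA,Link_TSG6,ITC,1.46,0.96,1.04,-8.23,-8.06,-0.16,Yes
HA8,3APY,Link_TSG6,ITC,0.27,0.03,1.19,-8.97,-5.70,-3.28,Yes
HA8,4AI,Link_TSG6,ITC,0.22,0.05,1.01,-9.15,-7.02,-2.13,Yes
HA8,5AI,Link_TSG6,ITC,0.15,0.03,0.97,-9.34,-7.43,-1.91,Yes
HA8,,CD44_HABD,MST,51.0,5,,,,,Yes
HA8,2AA,CD44_HABD,MST,108,2,,,,,Yes
HA8,3AA,CD44_HABD,MST,399,6,,,,,Yes
HA8,4AA,CD44_HABD,MST,478,5,,,,,Yes
HA8,2A4MBA,CD44_HABD,MST,36,9,,,,,Yes
HA8,3APY,CD44_HABD,MST,220,22,,,,,Yes
HA8,4AI,CD44_HABD,MST,139,43,,,,,Yes
HA8,5AI,CD44_HABD,MST,54,10,,,,,Yes
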