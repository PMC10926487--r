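site_id,lat,lon,utc_offset,date,sunrise_utc,sunset_utc,dusk_civil_utc,dusk_nautical_utc,dusk_astro_utc
kosci_summit,-36.456,148.263,11,2021-02-18,2021-02-17T19:41:25,2021-02-18T08:59:40,2021-02-18T09:26:32,2021-02-18T09:58:36,2021-02-18T10:32:06
kosci_summit,-36.456,148.263,11,2020-11-27,2020-11-26T18:43:29,2020-11-27T09:06:02,2020-11-27T09:35:40,2020-11-27T10:12:09,2020-11-27T10:52:13
mt_gingera,-35.573,148.777,11,2020-10-22,2020-10-21T19:13:00,2020-10-22T08:26:16,2020-10-22T08:52:47,2020-10-22T09:24:25,2020-10-22T09:57:20
kg_bogong,-36.517,148.283,11,2021-01-24,2021-01-23T19:14:20,2021-01-24T09:22:58,2021-01-24T09:51:48,2021-01-24T10:27:02,2021-01-24T11:05:08
equator,0.0,0.0,0,2021-03-20,2021-03-20T06:04:08,2021-03-20T18:10:39,2021-03-20T18:31:19,2021-03-20T18:55:19,2021-03-20T19:19:18
lund,55.705,13.191,1,2021-03-01,2021-03-01T05:57:56,2021-03-01T16:42:06,2021-03-01T17:19:14,2021-03-01T18:01:56,2021-03-01T18:45:11
canberra,-35.282,149.129,10,2020-07-15,2020-07-14T21:09:38,2020-07-15T07:09:33,2020-07-15T07:37:17,2020-07-15T08:08:35,2020-07-15T08:39:10
cabramurra,-35.936,148.38,11,2019-11-15,2019-11-14T18:50:58,2019-11-15T08:51:25,2019-11-15T09:19:48,2019-11-15T09:54:20,2019-11-15T10:31:28
quito,-0.18,-78.467,-5,2021-09-22,2021-09-22T11:03:10,2021-09-22T23:09:39,2021-09-22T23:30:19,2021-09-22T23:54:19,2021-09-23T00:18:19
hobart,-42.882,147.324,11,2021-12-21,2021-12-20T18:28:08,2021-12-21T09:49:13,2021-12-21T10:24:31,2021-12-21T11:10:23,2021-12-21T12:07:08
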